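// Recurrent language model core: batched forward/backward for SRN and LSTM
// encoders with a word decoder and an optional supertag decoder, trained by
// SGD with full backpropagation through time over padded sentence batches.
//
// Conventions shared with the R wrappers:
//  * token ids arrive 1-based from R and are converted to 0-based here;
//  * every sentence is framed as input [BOS, w1..wn] with word targets
//    [w1..wn, EOS]; the supertag target at input position i is the tag of the
//    current input word (so position 0, whose input is BOS, carries no tag);
//  * losses are accumulated in nats; surprisal is returned in bits;
//  * the optional projection matrix (ablation mask or nullspace projector) is
//    applied to the final-layer hidden state before both decoders.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

constexpr double LOG2E = 1.4426950408889634; // 1/log(2)

struct Net {
  mat emb;                 // V x D
  std::vector<mat> W;      // per layer: (4H|H) x (Din + H)
  std::vector<vec> b;
  mat dec_w;               // V x H
  vec dec_b;
  bool has_tag = false;
  mat tag_w;               // T x H
  vec tag_b;
  bool lstm = true;
  int L = 0, H = 0, D = 0, V = 0, Tn = 0;
};

Net unpack(const List& params, const std::string& arch) {
  Net n;
  n.lstm = (arch == "lstm");
  n.emb = as<mat>(params["emb"]);
  List Ws = params["Ws"], bs = params["bs"];
  n.L = Ws.size();
  for (int l = 0; l < n.L; ++l) {
    n.W.push_back(as<mat>(Ws[l]));
    n.b.push_back(as<vec>(bs[l]));
  }
  n.dec_w = as<mat>(params["dec_w"]);
  n.dec_b = as<vec>(params["dec_b"]);
  if (params.containsElementNamed("tag_w") &&
      !Rf_isNull(params["tag_w"])) {
    n.has_tag = true;
    n.tag_w = as<mat>(params["tag_w"]);
    n.tag_b = as<vec>(params["tag_b"]);
    n.Tn = n.tag_w.n_rows;
  }
  n.V = n.emb.n_rows;
  n.D = n.emb.n_cols;
  n.H = n.dec_w.n_cols;
  return n;
}

NumericVector as_rvec(const vec& v) {
  return NumericVector(v.begin(), v.end());
}

List pack(const Net& n) {
  List Ws(n.L), bs(n.L);
  for (int l = 0; l < n.L; ++l) { Ws[l] = n.W[l]; bs[l] = as_rvec(n.b[l]); }
  List out = List::create(_["emb"] = n.emb, _["Ws"] = Ws, _["bs"] = bs,
                          _["dec_w"] = n.dec_w,
                          _["dec_b"] = as_rvec(n.dec_b));
  if (n.has_tag) { out["tag_w"] = n.tag_w; out["tag_b"] = as_rvec(n.tag_b); }
  else { out["tag_w"] = R_NilValue; out["tag_b"] = R_NilValue; }
  return out;
}

struct Grad {
  mat emb;
  std::vector<mat> W;
  std::vector<vec> b;
  mat dec_w;
  vec dec_b;
  mat tag_w;
  vec tag_b;
  void zero_like(const Net& n) {
    emb.zeros(n.V, n.D);
    W.clear(); b.clear();
    for (int l = 0; l < n.L; ++l) {
      W.push_back(mat(n.W[l].n_rows, n.W[l].n_cols, arma::fill::zeros));
      b.push_back(vec(n.b[l].n_elem, arma::fill::zeros));
    }
    dec_w.zeros(n.V, n.H);
    dec_b.zeros(n.V);
    if (n.has_tag) { tag_w.zeros(n.Tn, n.H); tag_b.zeros(n.Tn); }
  }
  double sqnorm(const Net& n) const {
    double s = arma::accu(emb % emb);
    for (size_t l = 0; l < W.size(); ++l)
      s += arma::accu(W[l] % W[l]) + arma::accu(b[l] % b[l]);
    s += arma::accu(dec_w % dec_w) + arma::accu(dec_b % dec_b);
    if (n.has_tag) s += arma::accu(tag_w % tag_w) + arma::accu(tag_b % tag_b);
    return s;
  }
};

// One padded batch of sentences.
struct Batch {
  arma::imat in;     // B x T input ids (0-based), -1 at padding
  arma::imat tgt;    // B x T word targets, -1 at padding
  arma::imat tagtgt; // B x T tag targets, -1 where absent/masked
  arma::mat mask;    // B x T, 1 at real positions
  arma::mat tagmask; // B x T
  int B = 0, T = 0;
};

Batch make_batch(const std::vector<std::vector<int>>& sents,
                 const std::vector<std::vector<int>>& tags,
                 const std::vector<int>& idx, int bos, int eos,
                 bool use_tags) {
  Batch bt;
  bt.B = idx.size();
  int Tmax = 0;
  for (int i : idx) Tmax = std::max(Tmax, (int)sents[i].size() + 1);
  bt.T = Tmax;
  bt.in.set_size(bt.B, Tmax);  bt.in.fill(-1);
  bt.tgt.set_size(bt.B, Tmax); bt.tgt.fill(-1);
  bt.tagtgt.set_size(bt.B, Tmax); bt.tagtgt.fill(-1);
  bt.mask.zeros(bt.B, Tmax);
  bt.tagmask.zeros(bt.B, Tmax);
  for (int r = 0; r < bt.B; ++r) {
    const std::vector<int>& s = sents[idx[r]];
    int n = s.size();
    bt.in(r, 0) = bos;
    for (int t = 0; t < n; ++t) bt.in(r, t + 1) = s[t];
    for (int t = 0; t < n; ++t) bt.tgt(r, t) = s[t];
    bt.tgt(r, n) = eos;
    for (int t = 0; t <= n; ++t) bt.mask(r, t) = 1.0;
    if (use_tags) {
      const std::vector<int>& tg = tags[idx[r]];
      // tag target at input position t+1 is the tag of input word s[t]
      for (int t = 0; t < n; ++t) {
        if (tg[t] >= 0) {
          bt.tagtgt(r, t + 1) = tg[t];
          bt.tagmask(r, t + 1) = 1.0;
        }
      }
    }
  }
  return bt;
}

// Cached activations for one batch forward pass.
struct Cache {
  // per layer, per time step
  std::vector<std::vector<mat>> x;   // layer input
  std::vector<std::vector<mat>> h;   // hidden output
  std::vector<std::vector<mat>> i, f, g, o, c, tc; // lstm internals
  std::vector<std::vector<mat>> htop_proj;         // unused placeholder
};

// Forward pass. If `proj` is non-null it is applied to the final hidden
// state before the decoders. Returns projected top states per t in `tops`.
void forward(const Net& net, const Batch& bt, const mat* proj,
             Cache& ca, std::vector<mat>& tops) {
  int B = bt.B, T = bt.T, H = net.H;
  ca.x.assign(net.L, {});
  ca.h.assign(net.L, {});
  ca.i.assign(net.L, {}); ca.f.assign(net.L, {}); ca.g.assign(net.L, {});
  ca.o.assign(net.L, {}); ca.c.assign(net.L, {}); ca.tc.assign(net.L, {});
  std::vector<mat> hprev(net.L, mat(B, H, arma::fill::zeros));
  std::vector<mat> cprev(net.L, mat(B, H, arma::fill::zeros));
  tops.clear();
  for (int t = 0; t < T; ++t) {
    // embed inputs
    mat x(B, net.D, arma::fill::zeros);
    for (int r = 0; r < B; ++r) {
      int id = bt.in(r, t);
      if (id >= 0) x.row(r) = net.emb.row(id);
    }
    mat layer_in = x;
    for (int l = 0; l < net.L; ++l) {
      ca.x[l].push_back(layer_in);
      mat z = arma::join_rows(layer_in, hprev[l]); // B x (Din+H)
      if (net.lstm) {
        mat pre = z * net.W[l].t();
        pre.each_row() += net.b[l].t();
        mat ig = 1.0 / (1.0 + arma::exp(-pre.cols(0, H - 1)));
        mat fg = 1.0 / (1.0 + arma::exp(-pre.cols(H, 2 * H - 1)));
        mat gg = arma::tanh(pre.cols(2 * H, 3 * H - 1));
        mat og = 1.0 / (1.0 + arma::exp(-pre.cols(3 * H, 4 * H - 1)));
        mat c = fg % cprev[l] + ig % gg;
        mat tc = arma::tanh(c);
        mat h = og % tc;
        ca.i[l].push_back(ig); ca.f[l].push_back(fg); ca.g[l].push_back(gg);
        ca.o[l].push_back(og); ca.c[l].push_back(cprev[l]); ca.tc[l].push_back(tc);
        ca.h[l].push_back(h);
        cprev[l] = c;
        hprev[l] = h;
        layer_in = h;
      } else {
        mat pre = z * net.W[l].t();
        pre.each_row() += net.b[l].t();
        mat h = arma::tanh(pre);
        ca.h[l].push_back(h);
        hprev[l] = h;
        layer_in = h;
      }
    }
    mat top = hprev[net.L - 1];
    if (proj) top = top * (*proj);
    tops.push_back(top);
  }
}

// Row-wise log-softmax cross entropy; fills dlogits (same size as logits)
// with (softmax - onehot) restricted to masked rows; accumulates loss.
double xent_block(const mat& logits, const arma::imat& tgt,
                  const arma::mat& mask, int t, mat* dlogits,
                  double* correct, arma::ivec* pred) {
  int B = logits.n_rows;
  double loss = 0.0;
  for (int r = 0; r < B; ++r) {
    if (mask(r, t) <= 0) continue;
    rowvec row = logits.row(r);
    double m = row.max();
    rowvec ex = arma::exp(row - m);
    double Z = arma::accu(ex);
    rowvec p = ex / Z;
    int y = tgt(r, t);
    double py = p(y);
    loss += -(std::log(py > 0 ? py : 1e-300));
    if (pred) (*pred)(r) = p.index_max();
    if (correct && (int)p.index_max() == y) *correct += 1.0;
    if (dlogits) {
      dlogits->row(r) = p;
      (*dlogits)(r, y) -= 1.0;
    }
  }
  return loss;
}

std::vector<std::vector<int>> as_id_list(const List& sents) {
  std::vector<std::vector<int>> out;
  out.reserve(sents.size());
  for (int i = 0; i < sents.size(); ++i) {
    IntegerVector v = sents[i];
    std::vector<int> s(v.size());
    for (int j = 0; j < v.size(); ++j) s[j] = v[j] - 1; // to 0-based
    out.push_back(std::move(s));
  }
  return out;
}

// Backward through one batch given per-timestep decoder gradients on the
// (projected) top state. dtops[t] is B x H. Accumulates into gr.
void backward(const Net& net, const Batch& bt, const Cache& ca,
              const std::vector<mat>& dtops, const mat* proj, Grad& gr) {
  int B = bt.B, T = bt.T, H = net.H;
  // gradients flowing into each layer's h at each t from the layer above
  std::vector<std::vector<mat>> dh_from_above(net.L);
  for (int l = 0; l < net.L; ++l)
    dh_from_above[l].assign(T, mat(B, H, arma::fill::zeros));
  for (int t = 0; t < T; ++t) {
    mat d = dtops[t];
    if (proj) d = d * proj->t();
    dh_from_above[net.L - 1][t] += d;
  }
  for (int l = net.L - 1; l >= 0; --l) {
    int Din = ca.x[l][0].n_cols;
    mat dh_rec(B, H, arma::fill::zeros);
    mat dc_next(B, H, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      mat dh = dh_from_above[l][t] + dh_rec;
      mat hprev = (t > 0) ? ca.h[l][t - 1] : mat(B, H, arma::fill::zeros);
      mat z = arma::join_rows(ca.x[l][t], hprev);
      mat dz;
      if (net.lstm) {
        const mat& ig = ca.i[l][t]; const mat& fg = ca.f[l][t];
        const mat& gg = ca.g[l][t]; const mat& og = ca.o[l][t];
        const mat& cprev = ca.c[l][t]; const mat& tc = ca.tc[l][t];
        mat dog = dh % tc;
        mat dc = dh % og % (1.0 - tc % tc) + dc_next;
        mat dig = dc % gg;
        mat dgg = dc % ig;
        mat dfg = dc % cprev;
        dc_next = dc % fg;
        mat dpre(B, 4 * H);
        dpre.cols(0, H - 1) = dig % ig % (1.0 - ig);
        dpre.cols(H, 2 * H - 1) = dfg % fg % (1.0 - fg);
        dpre.cols(2 * H, 3 * H - 1) = dgg % (1.0 - gg % gg);
        dpre.cols(3 * H, 4 * H - 1) = dog % og % (1.0 - og);
        gr.W[l] += dpre.t() * z;
        gr.b[l] += arma::sum(dpre, 0).t();
        dz = dpre * net.W[l];
      } else {
        const mat& h = ca.h[l][t];
        mat dpre = dh % (1.0 - h % h);
        gr.W[l] += dpre.t() * z;
        gr.b[l] += arma::sum(dpre, 0).t();
        dz = dpre * net.W[l];
      }
      mat dx = dz.cols(0, Din - 1);
      dh_rec = dz.cols(Din, Din + H - 1);
      if (l > 0) {
        dh_from_above[l - 1][t] += dx;
      } else {
        for (int r = 0; r < B; ++r) {
          int id = bt.in(r, t);
          if (id >= 0) gr.emb.row(id) += dx.row(r);
        }
      }
    }
  }
}

// Compute combined loss and (optionally) gradients for one batch.
// Returns word loss sum (nats), tag loss sum, token counts via refs.
double batch_loss_grad(const Net& net, const Batch& bt, double w_word,
                       double w_tag, Grad* gr, double& wloss, double& nw,
                       double& tloss, double& nt) {
  Cache ca;
  std::vector<mat> tops;
  forward(net, bt, nullptr, ca, tops);
  wloss = 0; tloss = 0;
  nw = arma::accu(bt.mask);
  nt = net.has_tag ? arma::accu(bt.tagmask) : 0.0;
  std::vector<mat> dtops(bt.T, mat(bt.B, net.H, arma::fill::zeros));
  for (int t = 0; t < bt.T; ++t) {
    mat logits = tops[t] * net.dec_w.t();
    logits.each_row() += net.dec_b.t();
    mat dlog(bt.B, net.V, arma::fill::zeros);
    wloss += xent_block(logits, bt.tgt, bt.mask, t,
                        gr ? &dlog : nullptr, nullptr, nullptr);
    if (gr && nw > 0) {
      dlog *= w_word / nw;
      gr->dec_w += dlog.t() * tops[t];
      gr->dec_b += arma::sum(dlog, 0).t();
      dtops[t] += dlog * net.dec_w;
    }
    if (net.has_tag && nt > 0) {
      mat tlogits = tops[t] * net.tag_w.t();
      tlogits.each_row() += net.tag_b.t();
      mat dtl(bt.B, net.Tn, arma::fill::zeros);
      tloss += xent_block(tlogits, bt.tagtgt, bt.tagmask, t,
                          gr ? &dtl : nullptr, nullptr, nullptr);
      if (gr) {
        dtl *= w_tag / nt;
        gr->tag_w += dtl.t() * tops[t];
        gr->tag_b += arma::sum(dtl, 0).t();
        dtops[t] += dtl * net.tag_w;
      }
    }
  }
  if (gr) backward(net, bt, ca, dtops, nullptr, *gr);
  double combined = (nw > 0 ? w_word * wloss / nw : 0.0) +
                    (net.has_tag && nt > 0 ? w_tag * tloss / nt : 0.0);
  return combined;
}

void sgd_update(Net& net, const Grad& gr, double lr, double clip) {
  double scale = lr;
  if (clip > 0) {
    double nrm = std::sqrt(gr.sqnorm(net));
    if (nrm > clip) scale = lr * clip / nrm;
  }
  net.emb -= scale * gr.emb;
  for (int l = 0; l < net.L; ++l) {
    net.W[l] -= scale * gr.W[l];
    net.b[l] -= scale * gr.b[l];
  }
  net.dec_w -= scale * gr.dec_w;
  net.dec_b -= scale * gr.dec_b;
  if (net.has_tag) {
    net.tag_w -= scale * gr.tag_w;
    net.tag_b -= scale * gr.tag_b;
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_rnn_train(List params, std::string arch, List sents,
                   Nullable<List> tags_, int bos, int eos, int epochs,
                   double lr, double lr_decay, int batch_size,
                   double w_word, double w_tag, int seed, double clip) {
  Net net = unpack(params, arch);
  std::vector<std::vector<int>> xs = as_id_list(sents);
  std::vector<std::vector<int>> tg;
  bool use_tags = net.has_tag && tags_.isNotNull() && w_tag > 0;
  if (net.has_tag && tags_.isNotNull()) tg = as_id_list(List(tags_));
  int N = xs.size();
  // length-sorted batch composition (stable), shuffled batch order per epoch
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return xs[a].size() < xs[b].size();
  });
  std::vector<std::vector<int>> batches;
  for (int s = 0; s < N; s += batch_size) {
    std::vector<int> idx(order.begin() + s,
                         order.begin() + std::min(N, s + batch_size));
    batches.push_back(idx);
  }
  std::mt19937 rng(seed);
  NumericVector ep_word(epochs), ep_tag(epochs), ep_lr(epochs);
  bool diverged = false;
  double prev_loss = R_PosInf;
  for (int ep = 0; ep < epochs && !diverged; ++ep) {
    std::shuffle(batches.begin(), batches.end(), rng);
    double wl = 0, tl = 0, nw = 0, nt = 0;
    for (auto& idx : batches) {
      Batch bt = make_batch(xs, tg, idx, bos - 1, eos - 1,
                            use_tags && !tg.empty());
      Grad gr; gr.zero_like(net);
      double bwl, bnw, btl, bnt;
      double comb = batch_loss_grad(net, bt, w_word, use_tags ? w_tag : 0.0,
                                    &gr, bwl, bnw, btl, bnt);
      if (!std::isfinite(comb)) { diverged = true; break; }
      sgd_update(net, gr, lr, clip);
      wl += bwl; nw += bnw; tl += btl; nt += bnt;
      Rcpp::checkUserInterrupt();
    }
    ep_word[ep] = nw > 0 ? wl / nw : NA_REAL;
    ep_tag[ep] = nt > 0 ? tl / nt : NA_REAL;
    ep_lr[ep] = lr;
    double cur = (nw > 0 ? w_word * wl / nw : 0.0) +
                 (nt > 0 ? w_tag * tl / nt : 0.0);
    if (cur > prev_loss) lr *= 0.5; // anneal when training loss stalls
    prev_loss = cur;
    lr *= lr_decay;
  }
  return List::create(_["params"] = pack(net), _["word_loss"] = ep_word,
                      _["tag_loss"] = ep_tag, _["lr"] = ep_lr,
                      _["diverged"] = diverged);
}

// [[Rcpp::export]]
List cpp_rnn_eval(List params, std::string arch, List sents,
                  Nullable<List> tags_, int bos, int eos,
                  Nullable<NumericMatrix> proj_) {
  Net net = unpack(params, arch);
  std::vector<std::vector<int>> xs = as_id_list(sents);
  std::vector<std::vector<int>> tg;
  bool use_tags = net.has_tag && tags_.isNotNull();
  if (use_tags) tg = as_id_list(List(tags_));
  mat proj;
  const mat* projp = nullptr;
  if (proj_.isNotNull()) {
    proj = as<mat>(NumericMatrix(proj_));
    projp = &proj;
  }
  int N = xs.size();
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return xs[a].size() < xs[b].size();
  });
  double wloss = 0, nw = 0, tloss = 0, nt = 0, tcorrect = 0;
  List surp(N), tagpred(N);
  const int BS = 64;
  for (int s = 0; s < N; s += BS) {
    std::vector<int> idx(order.begin() + s,
                         order.begin() + std::min(N, s + BS));
    Batch bt = make_batch(xs, tg, idx, bos - 1, eos - 1, use_tags);
    Cache ca;
    std::vector<mat> tops;
    forward(net, bt, projp, ca, tops);
    std::vector<NumericVector> sv;
    std::vector<IntegerVector> pv;
    for (size_t r = 0; r < idx.size(); ++r) {
      sv.push_back(NumericVector((int)xs[idx[r]].size() + 1));
      pv.push_back(IntegerVector((int)xs[idx[r]].size()));
    }
    for (int t = 0; t < bt.T; ++t) {
      mat logits = tops[t] * net.dec_w.t();
      logits.each_row() += net.dec_b.t();
      for (int r = 0; r < bt.B; ++r) {
        if (bt.mask(r, t) <= 0) continue;
        rowvec row = logits.row(r);
        double m = row.max();
        rowvec ex = arma::exp(row - m);
        double logZ = m + std::log(arma::accu(ex));
        double lp = row(bt.tgt(r, t)) - logZ;
        wloss += -lp;
        nw += 1;
        sv[r][t] = -lp * LOG2E; // bits
      }
      if (use_tags) {
        mat tlogits = tops[t] * net.tag_w.t();
        tlogits.each_row() += net.tag_b.t();
        for (int r = 0; r < bt.B; ++r) {
          if (bt.tagmask(r, t) <= 0) continue;
          rowvec row = tlogits.row(r);
          double m = row.max();
          rowvec ex = arma::exp(row - m);
          double logZ = m + std::log(arma::accu(ex));
          int y = bt.tagtgt(r, t);
          tloss += -(row(y) - logZ);
          nt += 1;
          int ph = row.index_max();
          if (ph == y) tcorrect += 1;
          pv[r][t - 1] = ph + 1; // back to 1-based tag ids
        }
      }
    }
    for (size_t r = 0; r < idx.size(); ++r) {
      surp[idx[r]] = sv[r];
      if (use_tags) tagpred[idx[r]] = pv[r];
    }
  }
  return List::create(
      _["word_loss_sum"] = wloss, _["n_word"] = nw,
      _["tag_loss_sum"] = tloss, _["n_tag"] = nt,
      _["tag_correct"] = tcorrect, _["surprisal"] = surp,
      _["tag_pred"] = use_tags ? SEXP(tagpred) : R_NilValue);
}

// Final-layer hidden states for a single sentence: rows are positions
// 0..n corresponding to inputs [BOS, w1..wn]. No projection applied.
// [[Rcpp::export]]
NumericMatrix cpp_rnn_hidden(List params, std::string arch,
                             IntegerVector ids, int bos) {
  Net net = unpack(params, arch);
  std::vector<std::vector<int>> xs(1);
  for (int j = 0; j < ids.size(); ++j) xs[0].push_back(ids[j] - 1);
  std::vector<int> idx{0};
  std::vector<std::vector<int>> tg;
  Batch bt = make_batch(xs, tg, idx, bos - 1, /*eos*/ bos - 1, false);
  Cache ca;
  std::vector<mat> tops;
  forward(net, bt, nullptr, ca, tops);
  mat out(bt.T, net.H);
  for (int t = 0; t < bt.T; ++t) out.row(t) = tops[t].row(0);
  return wrap(out);
}

// Combined loss and analytic gradients over all given sentences as one
// batch set; used by the finite-difference gradient checks.
// [[Rcpp::export]]
List cpp_rnn_loss_grad(List params, std::string arch, List sents,
                       Nullable<List> tags_, int bos, int eos,
                       double w_word, double w_tag) {
  Net net = unpack(params, arch);
  std::vector<std::vector<int>> xs = as_id_list(sents);
  std::vector<std::vector<int>> tg;
  bool use_tags = net.has_tag && tags_.isNotNull() && w_tag > 0;
  if (net.has_tag && tags_.isNotNull()) tg = as_id_list(List(tags_));
  std::vector<int> idx(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) idx[i] = i;
  Batch bt = make_batch(xs, tg, idx, bos - 1, eos - 1,
                        use_tags && !tg.empty());
  Grad gr; gr.zero_like(net);
  double wl, nw, tl, nt;
  double comb = batch_loss_grad(net, bt, w_word, use_tags ? w_tag : 0.0,
                                &gr, wl, nw, tl, nt);
  List Ws(net.L), bs(net.L);
  for (int l = 0; l < net.L; ++l) { Ws[l] = gr.W[l]; bs[l] = as_rvec(gr.b[l]); }
  List grads = List::create(_["emb"] = gr.emb, _["Ws"] = Ws, _["bs"] = bs,
                            _["dec_w"] = gr.dec_w,
                            _["dec_b"] = as_rvec(gr.dec_b));
  if (net.has_tag) { grads["tag_w"] = gr.tag_w;
                     grads["tag_b"] = as_rvec(gr.tag_b); }
  return List::create(_["loss"] = comb, _["grads"] = grads,
                      _["word_loss"] = nw > 0 ? wl / nw : NA_REAL,
                      _["tag_loss"] = nt > 0 ? tl / nt : NA_REAL);
}
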