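#' Regression specification
#'
#' Declares the mixed-effects analysis for a trial table. All two-level
#' factors are sum-to-zero coded as numeric +/-0.5 contrasts with a fixed
#' "marked" level mapped to +0.5 (`mismatch`, `sg` subjects, `pp`
#' modifiers, `ungram`, `oblique`, `distributive`, plural `closer_number`);
#' coefficient magnitudes depend on this coding, so it is fixed
#' package-wide and documented here. With this coding and a balanced
#' design, the intercept equals the grand mean on the link scale and each
#' main-effect coefficient equals the full difference between its two
#' levels' means (on the link scale), divided by 1.
#'
#' @param response name of the response column (e.g. `"p_error"`,
#'   `"surprisal"`, `"p_plural"`).
#' @param fixed right-hand-side formula string for the fixed effects, e.g.
#'   `"attractor_match * subject_number"`.
#' @param random_intercepts subset of `c("item", "instance")`.
#' @param random_slopes named list mapping a grouping factor to the fixed
#'   terms whose slopes vary by that group (used as the maximal starting
#'   model for [prune_random_effects()]).
#' @return An object of class `regression_spec`.
#' @export
regression_spec <- function(response, fixed,
                            random_intercepts = c("item", "instance"),
                            random_slopes = list()) {
  stopifnot(is.character(response), is.character(fixed))
  stopifnot(all(random_intercepts %in% c("item", "instance")))
  stopifnot(all(names(random_slopes) %in% random_intercepts))
  structure(list(response = response, fixed = fixed,
                 random_intercepts = random_intercepts,
                 random_slopes = random_slopes),
            class = "regression_spec")
}

# Marked (+0.5) level per known two-level factor.
#' @noRd
marked_levels <- c(attractor_match = "mismatch", subject_number = "sg",
                   modifier = "pp", grammaticality = "ungram",
                   argument = "oblique", preposition_bias = "distributive",
                   syn_match = "mismatch", lin_match = "mismatch",
                   closer_number = "pl")

#' @noRd
sanitize_term <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

# Build the numeric sum-coded design for the fixed part of a spec.
# Every term (including interactions) becomes its own numeric column so
# equality constraints between coefficients reduce to column arithmetic.
#' @noRd
build_design <- function(data, fixed) {
  trm <- stats::terms(stats::reformulate(fixed))
  labels <- attr(trm, "term.labels")
  vars <- unique(unlist(strsplit(labels, ":", fixed = TRUE)))
  base <- list()
  for (v in vars) {
    if (!v %in% names(data))
      stop("fixed-effect variable not in data: ", v, call. = FALSE)
    col <- data[[v]]
    if (is.numeric(col)) {
      base[[v]] <- col
    } else {
      lev <- sort(unique(as.character(col)))
      if (length(lev) > 2)
        stop("factor `", v, "` has more than two levels; only two-level ",
             "factors are supported", call. = FALSE)
      pos <- if (v %in% names(marked_levels) &&
                 marked_levels[[v]] %in% lev) marked_levels[[v]] else lev[1]
      base[[v]] <- ifelse(as.character(col) == pos, 0.5, -0.5)
    }
  }
  design <- data.frame(row.names = seq_len(nrow(data)))
  map <- data.frame(term = labels, col = sanitize_term(labels),
                    stringsAsFactors = FALSE)
  for (i in seq_along(labels)) {
    parts <- strsplit(labels[i], ":", fixed = TRUE)[[1]]
    design[[map$col[i]]] <- Reduce(`*`, base[parts])
  }
  list(design = design, map = map)
}

#' @noRd
re_formula_part <- function(spec, map) {
  parts <- character(0)
  for (g in spec$random_intercepts) {
    slopes <- spec$random_slopes[[g]]
    if (length(slopes)) {
      cols <- map$col[match(slopes, map$term)]
      if (anyNA(cols))
        stop("random slope term(s) not among fixed terms", call. = FALSE)
      parts <- c(parts, sprintf("(1 + %s | %s)",
                                paste(cols, collapse = " + "), g))
    } else {
      parts <- c(parts, sprintf("(1 | %s)", g))
    }
  }
  parts
}

# Squeeze transform used only when responses touch 0/1 exactly:
# y' = (y (N - 1) + 0.5) / N.
#' @noRd
squeeze01 <- function(y) {
  if (any(y <= 0 | y >= 1)) {
    n <- length(y)
    y <- (y * (n - 1) + 0.5) / n
  }
  y
}

#' @noRd
fit_result <- function(kind, fit, spec, map, frame, converged,
                       flags = character(0)) {
  if (kind == "beta") {
    sm <- summary(fit)$coefficients$cond
    coefs <- data.frame(term = c("(Intercept)", map$term),
                        estimate = sm[, 1], se = sm[, 2],
                        statistic = sm[, 3], p = sm[, 4],
                        row.names = NULL)
    stat_type <- "z"
    disp <- sigma(fit)
    vc <- glmmTMB::VarCorr(fit)$cond
    re_var <- vapply(vc, function(m) m[1, 1], numeric(1))
  } else if (inherits(fit, "lmerMod")) {
    sm <- coef(summary(fit))
    coefs <- data.frame(term = c("(Intercept)", map$term),
                        estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"],
                        statistic = sm[, "t value"], row.names = NULL)
    coefs$p <- 2 * pnorm(-abs(coefs$statistic))
    stat_type <- "t (p from normal approximation)"
    disp <- sigma(fit)^2
    vc <- lme4::VarCorr(fit)
    re_var <- vapply(vc, function(m) m[1, 1], numeric(1))
  } else { # lm
    sm <- coef(suppressWarnings(summary(fit)))
    est <- coef(fit)
    coefs <- data.frame(term = c("(Intercept)", map$term),
                        estimate = est,
                        se = sm[match(names(est), rownames(sm)), 2],
                        statistic = sm[match(names(est), rownames(sm)), 3],
                        row.names = NULL)
    coefs$p <- 2 * pnorm(-abs(coefs$statistic))
    stat_type <- "t (p from normal approximation)"
    disp <- sigma(fit)^2
    re_var <- numeric(0)
  }
  structure(list(kind = kind, coefficients = coefs, stat_type = stat_type,
                 dispersion = disp, ranef_variance = re_var,
                 loglik = as.numeric(logLik(fit)), converged = converged,
                 flags = flags, spec = spec, map = map, frame = frame,
                 fit = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s regression (%s), %sconverged\n", x$kind,
              x$stat_type, if (x$converged) "" else "NOT "))
  print(x$coefficients, digits = 4)
  if (length(x$ranef_variance)) {
    cat("random-intercept variances:\n")
    print(x$ranef_variance, digits = 4)
  }
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @noRd
fit_engine <- function(kind, frame, spec, map, reml = TRUE) {
  fx <- if (nrow(map)) paste(map$col, collapse = " + ") else "1"
  re <- re_formula_part(spec, map)
  flags <- character(0)
  if (kind == "beta") {
    f <- as.formula(paste(".response ~", paste(c(fx, re), collapse = " + ")))
    warned <- FALSE
    fit <- withCallingHandlers(
      glmmTMB::glmmTMB(f, data = frame, family = glmmTMB::beta_family()),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    converged <- isTRUE(fit$fit$convergence == 0) &&
      isTRUE(fit$sdr$pdHess) && !warned
  } else if (length(re)) {
    f <- as.formula(paste(".response ~", paste(c(fx, re), collapse = " + ")))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(f, data = frame, REML = reml)))
    msgs <- fit@optinfo$conv$lme4$messages
    singular <- lme4::isSingular(fit, tol = 1e-4)
    if (singular) flags <- c(flags, "singular random-effect variance")
    converged <- is.null(msgs) && !singular
  } else {
    f <- as.formula(paste(".response ~", fx))
    fit <- lm(f, data = frame)
    converged <- TRUE
  }
  if (kind == "linear" && var(frame$.response) == 0)
    flags <- c(flags, "zero residual variance (constant response)")
  fit_result(kind, fit, spec, map, frame, converged, flags)
}

# Random-intercept groups need at least two levels; drop (and flag) any
# that do not, rather than letting the backend error.
#' @noRd
drop_single_level_groups <- function(data, spec) {
  flags <- character(0)
  for (g in spec$random_intercepts) {
    if (g %in% names(data) && length(unique(data[[g]])) < 2) {
      spec$random_intercepts <- setdiff(spec$random_intercepts, g)
      spec$random_slopes[[g]] <- NULL
      flags <- c(flags, sprintf(
        "dropped random intercept for `%s` (fewer than 2 levels)", g))
    }
  }
  list(spec = spec, flags = flags)
}

#' @noRd
prepare_frame <- function(data, spec, kind) {
  y <- data[[spec$response]]
  if (!is.numeric(y)) stop("response must be numeric", call. = FALSE)
  if (kind == "beta") {
    y <- squeeze01(y)
    if (var(y) == 0)
      stop("degenerate input: all probability responses identical after ",
           "the squeeze transform", call. = FALSE)
    if (any(y <= 0 | y >= 1))
      stop("probability responses must lie strictly inside (0, 1) after ",
           "the squeeze transform", call. = FALSE)
  }
  bd <- build_design(data, spec$fixed)
  frame <- bd$design
  frame$.response <- y
  for (g in spec$random_intercepts) {
    if (!g %in% names(data))
      stop("grouping column not in data: ", g, call. = FALSE)
    frame[[g]] <- factor(data[[g]])
  }
  list(frame = frame, map = bd$map)
}

#' Beta mixed-effects regression for probability responses
#'
#' Maximum-likelihood beta regression in the mean/precision
#' parameterization with a logit link for the mean and a log link for the
#' precision, with optional random intercepts (and slopes) integrated by
#' the Laplace approximation. Fixed-effect significance is assessed by
#' Wald z tests. Responses exactly at 0 or 1 are first squeezed by
#' `y' = (y (N - 1) + 0.5) / N`.
#'
#' @param data a trial table (e.g. from [run_production()]).
#' @param spec a [regression_spec()] with a probability response.
#' @return A `fit_result`.
#' @export
fit_beta_mixed <- function(data, spec) {
  ds <- drop_single_level_groups(data, spec)
  pf <- prepare_frame(data, ds$spec, "beta")
  out <- fit_engine("beta", pf$frame, ds$spec, pf$map)
  out$flags <- c(out$flags, ds$flags)
  out
}

#' Linear mixed-effects regression for surprisal responses
#'
#' Restricted maximum likelihood with random intercepts (and optional
#' slopes); per-coefficient t statistics, with p-values from a normal
#' approximation (flagged in the output).
#'
#' @param data a trial table (e.g. from [run_comprehension()]).
#' @param spec a [regression_spec()] with a numeric response.
#' @param reml use REML (default) or ML.
#' @return A `fit_result`.
#' @export
fit_linear_mixed <- function(data, spec, reml = TRUE) {
  ds <- drop_single_level_groups(data, spec)
  pf <- prepare_frame(data, ds$spec, "linear")
  out <- fit_engine("linear", pf$frame, ds$spec, pf$map, reml = reml)
  out$flags <- c(out$flags, ds$flags)
  out
}

#' Convergence-driven random-effect pruning
#'
#' Starting from the maximal model declared in `spec`, random-effect terms
#' are removed in a fixed, documented order until the fit converges:
#' highest-order (interaction) slopes first, then main-effect slopes
#' (instance slopes before item slopes at equal order), then the instance
#' intercept, and finally the item intercept (leaving a fixed-effects-only
#' model). The first converging fit is returned along with the pruning
#' path; if nothing converges the function errors with the full trace.
#'
#' @param data trial table.
#' @param spec maximal [regression_spec()].
#' @param kind `"beta"` or `"linear"`.
#' @return List with `fit` (a `fit_result`), `spec` (the pruned spec) and
#'   `path` (data frame of attempted structures).
#' @export
prune_random_effects <- function(data, spec, kind = c("beta", "linear")) {
  kind <- match.arg(kind)
  specs <- list(spec)
  cur <- spec
  repeat {
    ns <- cur
    # drop the highest-order slope, instance before item
    slopes <- lapply(c("instance", "item"), function(g)
      ns$random_slopes[[g]] %||% character(0))
    names(slopes) <- c("instance", "item")
    ord <- function(x) lengths(gregexpr(":", x, fixed = TRUE)) +
      as.integer(grepl(":", x, fixed = TRUE))
    dropped <- FALSE
    maxord <- max(c(-1L, unlist(lapply(slopes, function(s)
      if (length(s)) ord(s) else integer(0)))))
    if (maxord >= 0) {
      for (g in c("instance", "item")) {
        s <- slopes[[g]]
        hit <- which(if (length(s)) ord(s) == maxord else logical(0))
        if (length(hit)) {
          ns$random_slopes[[g]] <- s[-hit[length(hit)]]
          dropped <- TRUE
          break
        }
      }
    }
    if (!dropped) {
      if ("instance" %in% ns$random_intercepts) {
        ns$random_intercepts <- setdiff(ns$random_intercepts, "instance")
        ns$random_slopes$instance <- NULL
      } else if ("item" %in% ns$random_intercepts) {
        ns$random_intercepts <- setdiff(ns$random_intercepts, "item")
        ns$random_slopes$item <- NULL
      } else break
    }
    specs[[length(specs) + 1]] <- ns
    cur <- ns
  }
  path <- data.frame(step = seq_along(specs),
                     structure = vapply(specs, function(s) {
                       pf0 <- build_design(data[1, , drop = FALSE], s$fixed)
                       paste(re_formula_part(s, pf0$map) %||% "(none)",
                             collapse = " + ")
                     }, character(1)),
                     converged = NA)
  for (i in seq_along(specs)) {
    res <- tryCatch({
      if (kind == "beta") fit_beta_mixed(data, specs[[i]])
      else fit_linear_mixed(data, specs[[i]])
    }, error = function(e) NULL)
    path$converged[i] <- !is.null(res) && res$converged
    if (path$converged[i]) {
      path <- path[seq_len(i), , drop = FALSE]
      return(list(fit = res, spec = specs[[i]], path = path))
    }
  }
  stop("no random-effects structure converged; pruning path:\n",
       paste(utils::capture.output(print(path)), collapse = "\n"),
       call. = FALSE)
}

#' Equality-constraint likelihood-ratio test
#'
#' Tests whether two fixed effects are equal by comparing the fit of the
#' original model to a model in which the two coefficients are constrained
#' to be equal (their design columns are summed into one predictor). Both
#' models are fit by maximum likelihood; the statistic is
#' `2 (logLik_full - logLik_constrained)` referred to a chi-squared
#' distribution with 1 degree of freedom.
#'
#' @param fit a `fit_result` from [fit_beta_mixed()] or
#'   [fit_linear_mixed()].
#' @param term_a,term_b names of the two fixed-effect terms (as in
#'   `fit$coefficients$term`).
#' @return List with `statistic`, `df`, `p`, `loglik_full`,
#'   `loglik_constrained`.
#' @export
linear_hypothesis_test <- function(fit, term_a, term_b) {
  stopifnot(inherits(fit, "fit_result"))
  map <- fit$map
  for (tm in c(term_a, term_b))
    if (!tm %in% map$term)
      stop("term not in model: ", tm, call. = FALSE)
  frame <- fit$frame
  spec <- fit$spec
  refit <- function(map2, frame2) {
    fit_engine(fit$kind, frame2, spec, map2, reml = FALSE)
  }
  full <- refit(map, frame)
  if (term_a == term_b) {
    constrained <- full
  } else {
    ca <- map$col[map$term == term_a]
    cb <- map$col[map$term == term_b]
    newcol <- paste0(sanitize_term(paste0(ca, "_eq_", cb)))
    frame2 <- frame
    frame2[[newcol]] <- frame2[[ca]] + frame2[[cb]]
    frame2[[ca]] <- NULL
    frame2[[cb]] <- NULL
    map2 <- map[!map$term %in% c(term_a, term_b), , drop = FALSE]
    map2 <- rbind(map2, data.frame(term = paste(term_a, "=", term_b),
                                   col = newcol))
    constrained <- refit(map2, frame2)
  }
  stat <- max(0, 2 * (full$loglik - constrained$loglik))
  list(statistic = stat, df = 1L,
       p = pchisq(stat, df = 1, lower.tail = FALSE),
       loglik_full = full$loglik,
       loglik_constrained = constrained$loglik)
}
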