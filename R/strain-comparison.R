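#' Compare strains on a binary endpoint by logistic regression
#'
#' The workhorse behind the strain-level analyses: fits a binomial logistic
#' model of a per-worm binary outcome on strain (treatment coding against
#' the first strain level) and tests all pairwise strain contrasts on the
#' log-odds scale with Wald statistics. Familywise multiplicity is handled
#' by the single-step multivariate-normal adjustment — the standard
#' realization of Tukey-type all-pairs contrasts for generalized linear
#' models — computed from the joint normal distribution of the contrast
#' statistics; a Bonferroni fallback is used when the contrast correlation
#' matrix is ill-conditioned or the multivariate-normal probability fails.
#' Both raw and adjusted p-values are reported, and adjusted never falls
#' below raw.
#'
#' A strain with 0% or 100% outcomes makes the likelihood separate; the fit
#' then switches to a documented penalized form (0.5 pseudo-successes and
#' 0.5 pseudo-failures added to every strain's counts) and flags it.
#'
#' @param outcome logical (or 0/1) per-worm outcomes.
#' @param strain factor or character of strain labels, same length.
#' @param endpoint label stored with the result (e.g.
#'   `"reversal-at-tap-30"`, `"swimming-at-10-min"`).
#' @param adjust `"single-step"` (default) or `"bonferroni"`.
#' @param cluster optional grouping vector (e.g. plate) for a cluster-robust
#'   sandwich variance; plates may induce correlation that the worm-level
#'   model ignores.
#' @param level confidence level recorded with the fit.
#' @return a `strain_comparison` object; see [summary.strain_comparison()].
#' @examples
#' set.seed(1)
#' strain <- rep(c("N2", "mut"), each = 100)
#' y <- stats::rbinom(200, 1, ifelse(strain == "N2", 0.5, 0.1))
#' compare_strains(y, strain, endpoint = "reversal-at-tap-30")
#' @export
compare_strains <- function(outcome, strain, endpoint = "binary-endpoint",
                            adjust = c("single-step", "bonferroni"),
                            cluster = NULL, level = 0.95) {
  adjust <- match.arg(adjust)
  strain <- factor(strain)
  outcome <- as.logical(outcome)
  stopifnot(length(outcome) == length(strain))
  keep <- !is.na(outcome) & !is.na(strain)
  outcome <- outcome[keep]; strain <- droplevels(strain[keep])
  if (!is.null(cluster)) cluster <- cluster[keep]
  S <- nlevels(strain)
  if (S < 2L) stop("need at least 2 strains", call. = FALSE)
  counts <- table(strain, factor(outcome, c(FALSE, TRUE)))
  k <- counts[, "TRUE"]; n <- rowSums(counts)
  if (any(n < 1L)) stop("every strain needs at least one worm", call. = FALSE)

  separated <- any(k == 0L | k == n)
  if (separated) {
    # penalized fit: half a pseudo-success and pseudo-failure per strain
    dat <- data.frame(k = as.numeric(k) + 0.5, m = as.numeric(n - k) + 0.5,
                      strain = factor(levels(strain), levels(strain)))
    fit <- suppressWarnings(
      stats::glm(cbind(k, m) ~ strain, family = stats::binomial(),
                 data = dat))
    V <- stats::vcov(fit)
  } else if (!is.null(cluster)) {
    dat <- data.frame(y = outcome, strain = strain)
    fit <- stats::glm(y ~ strain, family = stats::binomial(), data = dat)
    V <- cluster_vcov(fit, cluster)
  } else {
    dat <- data.frame(k = as.numeric(k), m = as.numeric(n - k),
                      strain = factor(levels(strain), levels(strain)))
    fit <- stats::glm(cbind(k, m) ~ strain, family = stats::binomial(),
                      data = dat)
    V <- stats::vcov(fit)
  }
  beta <- stats::coef(fit)

  # all-pairs contrast matrix in the treatment-coded parameterization:
  # strain i vs strain j differs only in the dummy coefficients
  lev <- levels(strain)
  pairs <- utils::combn(S, 2)
  L <- matrix(0, ncol(pairs), length(beta),
              dimnames = list(NULL, names(beta)))
  lab <- character(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    if (i > 1L) L[q, i] <- -1   # column i is the dummy of level i (i >= 2)
    L[q, j] <- 1
    lab[q] <- paste(lev[j], "-", lev[i])
  }
  est <- drop(L %*% beta)
  cv <- L %*% V %*% t(L)
  se <- sqrt(diag(cv))
  z <- est / se
  p_raw <- 2 * stats::pnorm(-abs(z))
  adj <- adjust_pvalues(z, cv, adjust)
  p_adj <- pmax(pmin(adj$p, 1), p_raw)

  structure(list(endpoint = endpoint, strains = lev,
                 counts = data.frame(strain = lev, k = as.integer(k),
                                     n = as.integer(n),
                                     proportion = as.numeric(k / n)),
                 coefficients = beta, vcov = V,
                 contrasts = data.frame(contrast = lab, estimate = est,
                                        se = se, z = z, p_raw = p_raw,
                                        p_adj = p_adj),
                 adjustment = adj$method, separated = separated,
                 clustered = !is.null(cluster), level = level,
                 model = fit),
            class = "strain_comparison")
}

# single-step MVN adjustment: p_i = 1 - P(max_j |Z_j| <= |z_i|),
# Z ~ MVN(0, corr(contrast covariance)); Bonferroni when requested or when
# the correlation matrix is ill-conditioned / pmvnorm fails
adjust_pvalues <- function(z, cv, adjust) {
  m <- length(z)
  if (m == 1L) return(list(p = 2 * stats::pnorm(-abs(z)), method = "none"))
  if (adjust == "single-step") {
    # all-pairs contrast correlation is rank-deficient by construction
    # (rank S-1); pmvnorm handles the singular case
    R <- stats::cov2cor(cv)
    p <- vapply(abs(z), function(a) {
      pr <- tryCatch(
        mvtnorm::pmvnorm(lower = rep(-a, m), upper = rep(a, m), corr = R,
                         algorithm = mvtnorm::GenzBretz(abseps = 1e-6)),
        error = function(e) NA_real_)
      1 - as.numeric(pr)
    }, numeric(1))
    if (!anyNA(p) && all(is.finite(p))) return(list(p = p, method = "single-step"))
  }
  list(p = pmin(1, m * 2 * stats::pnorm(-abs(z))), method = "bonferroni")
}

# CR0 cluster-robust sandwich variance for a binomial glm (dispersion 1):
# scores X'(y - mu) summed within clusters, bread = (X'WX)^{-1} = vcov(fit)
cluster_vcov <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  scores <- X * (fit$prior.weights * stats::residuals(fit, type = "response"))
  meat <- crossprod(as.matrix(rowsum(scores, cluster)))
  bread <- stats::vcov(fit)
  bread %*% meat %*% bread
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat(sprintf("<strain_comparison> endpoint: %s (%d strains, %s adjustment%s)\n",
              x$endpoint, length(x$strains), x$adjustment,
              if (x$separated) ", penalized fit [separation]" else ""))
  df <- x$contrasts
  df$estimate <- round(df$estimate, 3); df$se <- round(df$se, 3)
  df$z <- round(df$z, 2)
  df$p_raw <- signif(df$p_raw, 3); df$p_adj <- signif(df$p_adj, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Summarize a strain comparison
#'
#' @param object a `strain_comparison`.
#' @param ... unused.
#' @return the object, invisibly; prints counts, log-odds coefficients and
#'   the contrast table.
#' @export
summary.strain_comparison <- function(object, ...) {
  cat("Endpoint:", object$endpoint, "\n\nPer-strain outcomes:\n")
  print.data.frame(object$counts, row.names = FALSE)
  cat("\nLog-odds coefficients (treatment coding vs", object$strains[1],
      "):\n")
  print(round(object$coefficients, 4))
  cat(sprintf("\nPairwise contrasts (log-odds scale, %s adjustment):\n",
              object$adjustment))
  print.data.frame(object$contrasts, row.names = FALSE)
  if (object$separated)
    cat("\nNote: separation detected; penalized (pseudo-count) fit used.\n")
  if (object$clustered)
    cat("Note: cluster-robust (sandwich) standard errors.\n")
  invisible(object)
}

#' @export
coef.strain_comparison <- function(object, ...) object$coefficients

#' Compare the habituated level (reversal at the final tap) across strains
#'
#' The habituated level is the proportion of worms still reversing at the
#' endpoint tap (tap 30 in the standard protocol, exactly — not an average
#' over final taps). Worms untracked at that tap are excluded. Fits the
#' logistic strain model of [compare_strains()] on those outcomes.
#'
#' @param events event table (see [habituation_curve()]).
#' @param endpoint_tap tap index of the endpoint.
#' @param min_worms minimum tracked worms per strain at the endpoint.
#' @param ... passed to [compare_strains()] (`adjust`, `cluster`, `level`).
#' @return a `strain_comparison`.
#' @export
compare_habituated_level <- function(events, endpoint_tap = 30L,
                                     min_worms = 5L, ...) {
  events <- as_event_table(events)
  sub <- events[events$tap_index == endpoint_tap & events$tracked, ]
  if (nrow(sub) == 0L)
    stop("no tracked worms at the endpoint tap", call. = FALSE)
  cnt <- table(sub$strain)
  if (length(cnt) < 2L) stop("need at least 2 strains", call. = FALSE)
  if (any(cnt < min_worms))
    stop(sprintf("every strain needs >= %d tracked worms at tap %d",
                 min_worms, endpoint_tap), call. = FALSE)
  args <- list(...)
  if (is.null(args$endpoint))
    args$endpoint <- sprintf("reversal-at-tap-%d", endpoint_tap)
  if (identical(args$cluster, "plate")) args$cluster <- sub$plate_id
  do.call(compare_strains,
          c(list(outcome = sub$reversed, strain = sub$strain), args))
}

#' Per-strain proportions with CIs plus the strain comparison
#'
#' Wraps [binomial_ci()] and the logistic machinery of [compare_strains()]
#' for single binary endpoints such as swimming at 10 min
#' (swimming-induced-paralysis assay) or responding to a mechanical
#' stimulus (calcium responder rates).
#'
#' @param outcome logical per-worm outcomes.
#' @param strain strain labels, same length.
#' @param endpoint label.
#' @param level confidence level.
#' @param ci_method [binomial_ci()] method.
#' @param ... passed to [compare_strains()].
#' @return a `proportion_endpoint`: list with `per_strain` (data.frame of
#'   proportions and CIs) and `comparison` (a `strain_comparison`, `NULL`
#'   with a single strain).
#' @export
proportion_endpoint <- function(outcome, strain, endpoint = "endpoint",
                                level = 0.95, ci_method = "wilson", ...) {
  strain <- factor(strain)
  outcome <- as.logical(outcome)
  keep <- !is.na(outcome)
  outcome <- outcome[keep]; strain <- droplevels(strain[keep])
  per <- do.call(rbind, lapply(levels(strain), function(s) {
    ci <- binomial_ci(sum(outcome[strain == s]), sum(strain == s),
                      level, ci_method)
    data.frame(strain = s, k = ci$numerator, n = ci$denominator,
               proportion = ci$proportion, ci_low = ci$ci_low,
               ci_high = ci$ci_high)
  }))
  cmp <- if (nlevels(strain) >= 2L)
    compare_strains(outcome, strain, endpoint = endpoint, level = level, ...)
  structure(list(endpoint = endpoint, per_strain = per, comparison = cmp,
                 ci_method = ci_method, level = level),
            class = "proportion_endpoint")
}

#' @export
print.proportion_endpoint <- function(x, ...) {
  cat(sprintf("<proportion_endpoint> %s (%s %g%% CIs)\n", x$endpoint,
              x$ci_method, 100 * x$level))
  print.data.frame(x$per_strain, row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat("\n"); print(x$comparison)
  }
  invisible(x)
}

#' Basal slowing summary: bend counts on versus off food
#'
#' Wild-type worms slow on a bacterial lawn; the slowing index of a strain
#' is `1 - mean(bends on food) / mean(bends off food)` over worms scored in
#' the standard 60-120 s window. A seeded nonparametric bootstrap over worms
#' gives the index interval; pairwise strain differences of the index are
#' reported with bootstrap intervals.
#'
#' @param bends data.frame with columns `strain`, `condition` (`"on_food"` /
#'   `"off_food"`) and `bends` (count per worm).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param level interval level.
#' @return a `slowing_summary`: list with `per_strain` (means, index,
#'   interval) and `pairwise` (index differences with intervals).
#' @export
basal_slowing_summary <- function(bends, n_boot = 2000L, seed = 1L,
                                  level = 0.95) {
  stopifnot(all(c("strain", "condition", "bends") %in% names(bends)))
  if (!all(bends$condition %in% c("on_food", "off_food")))
    stop('`condition` must be "on_food" or "off_food"', call. = FALSE)
  strains <- unique(bends$strain)
  for (s in strains) {
    cc <- unique(bends$condition[bends$strain == s])
    if (!all(c("on_food", "off_food") %in% cc))
      stop(sprintf("strain %s lacks one condition", s), call. = FALSE)
  }
  a <- 1 - level
  seeds <- derive_seeds(seed, length(strains))
  boot_idx <- list()
  per <- do.call(rbind, lapply(seq_along(strains), function(i) {
    s <- strains[i]
    on <- bends$bends[bends$strain == s & bends$condition == "on_food"]
    off <- bends$bends[bends$strain == s & bends$condition == "off_food"]
    if (mean(off) == 0)
      stop(sprintf("strain %s: off-food mean is zero, slowing index undefined", s),
           call. = FALSE)
    set.seed(seeds[i])
    bs <- replicate(n_boot, {
      moff <- mean(sample(off, replace = TRUE))
      if (moff == 0) NA_real_
      else 1 - mean(sample(on, replace = TRUE)) / moff
    })
    boot_idx[[s]] <<- bs
    q <- stats::quantile(bs, c(a / 2, 1 - a / 2), na.rm = TRUE)
    data.frame(strain = s, mean_on = mean(on), mean_off = mean(off),
               slowing_index = 1 - mean(on) / mean(off),
               ci_low = unname(q[1]), ci_high = unname(q[2]))
  }))
  pw <- NULL
  if (length(strains) >= 2L) {
    pr <- utils::combn(strains, 2, simplify = FALSE)
    pw <- do.call(rbind, lapply(pr, function(p) {
      d <- boot_idx[[p[1]]] - boot_idx[[p[2]]]
      q <- stats::quantile(d, c(a / 2, 1 - a / 2), na.rm = TRUE)
      data.frame(contrast = paste(p[1], "-", p[2]),
                 diff = per$slowing_index[per$strain == p[1]] -
                   per$slowing_index[per$strain == p[2]],
                 ci_low = unname(q[1]), ci_high = unname(q[2]))
    }))
  }
  structure(list(per_strain = per, pairwise = pw, n_boot = n_boot,
                 level = level, seed = seed),
            class = "slowing_summary")
}

#' @export
print.slowing_summary <- function(x, ...) {
  cat(sprintf("<slowing_summary> bootstrap %g%% intervals (%d replicates)\n",
              100 * x$level, x$n_boot))
  print.data.frame(x$per_strain, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("\nPairwise slowing-index differences:\n")
    print.data.frame(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}
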