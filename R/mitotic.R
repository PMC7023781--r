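#' Probability a mitotic cluster goes unsampled in a cohort
#'
#' Given that a mitotic exchange occurred, the cluster is missed when fewer
#' than `min_progeny` of the N sequenced progeny inherit the recombinant
#' chromatid: the binomial lower tail
#' `sum_{x=0}^{min_progeny-1} C(N,x) beta^x (1-beta)^(N-x)`. Cohorts with
#' `N <= min_progeny - 1` can never reveal a cluster, so the probability is
#' exactly 1 there.
#'
#' @param n cohort size(s).
#' @param beta transmission frequency in `[0, 1]`.
#' @param min_progeny carriers needed for the cluster to be observable.
#' @return Probability, vectorized over `n` and `beta`.
#' @export
p_cluster_not_sampled <- function(n, beta, min_progeny = 4L) {
  stopifnot(all(n >= 0), all(beta >= 0), all(beta <= 1))
  pmin(1, pmax(0, stats::pbinom(min_progeny - 1L, n, beta)))
}

#' Specify a mitotic-rate model
#'
#' The sharing pattern of alpha (cluster formation) and beta (transmission)
#' across the dysgenic and non-dysgenic conditions: `"shared"` uses one
#' value for both, `"split"` one per condition, giving the 2-, 3- and
#' 4-parameter models.
#'
#' @param alpha,beta `"shared"` or `"split"`.
#' @param min_progeny detection threshold used by the truncated term.
#' @param chromosomes chromosomes contributing one Bernoulli(alpha) trial
#'   per mother each (clusters were only ever seen on X and 3).
#' @param truncated if `TRUE`, condition the observed-cluster binomial term
#'   on `x >= min_progeny` (statistically truncated variant); the default
#'   `FALSE` uses the plain binomial term of the published model.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(alpha = c("shared", "split"),
                       beta = c("shared", "split"),
                       min_progeny = 4L,
                       chromosomes = c("X", "3"),
                       truncated = FALSE) {
  alpha <- match.arg(alpha); beta <- match.arg(beta)
  np <- 2L + (alpha == "split") + (beta == "split")
  structure(list(alpha = alpha, beta = beta,
                 min_progeny = as.integer(min_progeny),
                 chromosomes = chromosomes, truncated = truncated,
                 n_params = np),
            class = "model_spec")
}

free_params <- function(spec) {
  c(if (spec$alpha == "shared") "alpha" else c("alpha_dysgenic", "alpha_nondysgenic"),
    if (spec$beta == "shared") "beta" else c("beta_dysgenic", "beta_nondysgenic"))
}

resolve_params <- function(params, spec, condition) {
  a <- if (spec$alpha == "shared") rep(params[["alpha"]], length(condition))
       else unname(params[paste0("alpha_", condition)])
  b <- if (spec$beta == "shared") rep(params[["beta"]], length(condition))
       else unname(params[paste0("beta_", condition)])
  list(alpha = a, beta = b)
}

#' Log-likelihood of cohort observations under the mitotic model
#'
#' Each observation is one mother x chromosome: cohort size N and carrier
#' count x (0 when no cluster was seen). A mother without an observed
#' cluster contributes `(1 - alpha) + alpha * P(cluster not sampled)`; a
#' mother with an observed cluster contributes
#' `alpha * C(N,x) beta^x (1-beta)^(N-x)`. The total log-likelihood is the
#' sum of the logs of these factors.
#'
#' @param obs `data.table`/`data.frame` with columns `N`, `x`, `condition`
#'   (`"dysgenic"`/`"nondysgenic"`).
#' @param params named numeric vector over [free_params()] of `spec`, all
#'   in `[0, 1]`.
#' @param spec a [model_spec()].
#' @return Log-likelihood (may be `-Inf`).
#' @export
mitotic_loglik <- function(obs, params, spec = model_spec()) {
  if (any(params < 0 | params > 1)) stop("parameters must lie in [0, 1]")
  if (any(obs$x > obs$N)) stop("invalid data: x exceeds N")
  if (any(obs$x > 0 & obs$x < spec$min_progeny))
    stop("invalid data: observed carrier count below min_progeny")
  rp <- resolve_params(params, spec, obs$condition)
  seen <- obs$x >= spec$min_progeny
  ll <- numeric(nrow(obs))
  if (any(!seen)) {
    pns <- p_cluster_not_sampled(obs$N[!seen], rp$beta[!seen], spec$min_progeny)
    ll[!seen] <- log((1 - rp$alpha[!seen]) + rp$alpha[!seen] * pns)
  }
  if (any(seen)) {
    lb <- stats::dbinom(obs$x[seen], obs$N[seen], rp$beta[seen], log = TRUE)
    if (spec$truncated) {
      denom <- 1 - p_cluster_not_sampled(obs$N[seen], rp$beta[seen],
                                         spec$min_progeny)
      lb <- lb - log(denom)
    }
    ll[seen] <- log(rp$alpha[seen]) + lb
  }
  sum(ll)
}

#' Maximum-likelihood fit of the mitotic cluster model
#'
#' Bounded quasi-Newton (L-BFGS-B) maximization of [mitotic_loglik()] from
#' a deterministic 5 x 5 multi-start grid (alpha-type and beta-type
#' parameters each started at five values), parameters boxed to
#' `[1e-6, 1 - 1e-6]`. Deterministic given data and spec.
#'
#' @param obs cohort observations (see [mitotic_loglik()]).
#' @param spec a [model_spec()].
#' @return Object of class `mitotic_fit`: `estimates` (named vector),
#'   `loglik`, `spec`, `n_obs`, `convergence`, `data`.
#' @export
fit_mitotic <- function(obs, spec = model_spec()) {
  obs <- data.table::as.data.table(obs)
  if (nrow(obs) == 0L) stop("no observations")
  pn <- free_params(spec)
  for (cond in c("dysgenic", "nondysgenic")) {
    needs <- (spec$alpha == "split" || spec$beta == "split")
    if (needs && !cond %in% obs$condition)
      stop("split model requires observations from condition ", cond)
  }
  negll <- function(theta) {
    -mitotic_loglik(obs, stats::setNames(theta, pn), spec)
  }
  starts <- as.matrix(expand.grid(a = c(0.05, 0.275, 0.5, 0.725, 0.95),
                                  b = c(0.05, 0.275, 0.5, 0.725, 0.95)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- ifelse(grepl("^alpha", pn), starts[i, "a"], starts[i, "b"])
    o <- try(stats::optim(th0, negll, method = "L-BFGS-B",
                          lower = 1e-6, upper = 1 - 1e-6,
                          control = list(maxit = 500)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("mitotic fit failed to converge from any start")
  if (!any(obs$x >= spec$min_progeny)) {
    # with no observed cluster the likelihood is non-increasing in alpha for
    # every beta (flat when beta = 0); resolve the ridge to the boundary
    best$par[grepl("^alpha", pn)] <- 1e-6
    best$value <- -mitotic_loglik(obs, stats::setNames(best$par, pn), spec)
  }
  structure(list(estimates = stats::setNames(best$par, pn),
                 loglik = -best$value, spec = spec, n_obs = nrow(obs),
                 convergence = best$convergence, data = obs),
            class = "mitotic_fit")
}

#' @export
print.mitotic_fit <- function(x, ...) {
  cat(sprintf("Mitotic cluster model (%d parameters: alpha %s, beta %s)\n",
              x$spec$n_params, x$spec$alpha, x$spec$beta))
  print(round(x$estimates, 4))
  cat(sprintf("log-likelihood %.4f over %d mother-chromosome observations\n",
              x$loglik, x$n_obs))
  invisible(x)
}

#' Nested likelihood-ratio test between two fits
#'
#' @param fit_nested,fit_general [fit_mitotic()] results on the same data,
#'   with the nested spec a restriction of the general one.
#' @return List: `statistic`, `df`, `p`.
#' @export
compare_models <- function(fit_nested, fit_general) {
  sn <- fit_nested$spec; sg <- fit_general$spec
  nested_ok <- sg$n_params >= sn$n_params &&
    (sn$alpha == sg$alpha || sg$alpha == "split") &&
    (sn$beta == sg$beta || sg$beta == "split") &&
    sn$min_progeny == sg$min_progeny && sn$truncated == sg$truncated
  if (!nested_ok) stop("specs are not nested")
  if (fit_nested$n_obs != fit_general$n_obs)
    stop("fits must be on the same data")
  stat <- 2 * (fit_general$loglik - fit_nested$loglik)
  if (stat < -1e-6) stop("negative LRT statistic: optimizer failure")
  stat <- max(stat, 0)
  df <- sg$n_params - sn$n_params
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Two-unit-drop confidence interval for one parameter
#'
#' Scans the named parameter with the other parameters fixed at their
#' maximum-likelihood estimates and reports where the log-likelihood falls
#' `delta` units below its maximum (the published procedure; not a full
#' profile likelihood). Bounds are clipped to `[0, 1]`.
#'
#' @param fit a [fit_mitotic()] result.
#' @param param name of the parameter (one of `names(fit$estimates)`).
#' @param delta log-likelihood drop defining the interval.
#' @return List: `low`, `high`, `flat` (TRUE when the likelihood never
#'   drops by `delta` on a side).
#' @export
profile_ci <- function(fit, param, delta = 2) {
  if (!param %in% names(fit$estimates)) stop("unknown parameter ", param)
  th <- fit$estimates
  f <- function(v) {
    th[param] <- v
    mitotic_loglik(fit$data, th, fit$spec)
  }
  target <- fit$loglik - delta
  mle <- fit$estimates[[param]]
  lo_bound <- 1e-9; hi_bound <- 1 - 1e-9
  flat <- FALSE
  low <- if (f(lo_bound) < target) {
    stats::uniroot(function(v) f(v) - target, c(lo_bound, mle),
                   tol = 1e-9)$root
  } else { flat <- flat || (f(lo_bound) > target); 0 }
  high <- if (f(hi_bound) < target) {
    stats::uniroot(function(v) f(v) - target, c(mle, hi_bound),
                   tol = 1e-9)$root
  } else { flat <- flat || (f(hi_bound) > target); 1 }
  list(low = max(0, low), high = min(1, high), flat = flat)
}

#' Per-condition mitotic transmission rate (alpha x beta)
#'
#' @param fit a [fit_mitotic()] result.
#' @return Named numeric: expected mitotic crossovers per gamete per
#'   chromosome for `dysgenic` and `nondysgenic`.
#' @export
transmission_rate <- function(fit) {
  conds <- c("dysgenic", "nondysgenic")
  rp <- resolve_params(fit$estimates, fit$spec, conds)
  stats::setNames(rp$alpha * rp$beta, conds)
}

#' Build cohort observations from clusters and samples
#'
#' One observation per mother per estimation chromosome: N is the number of
#' sequenced progeny, x the carrier count of a detected cluster on that
#' chromosome (0 otherwise).
#'
#' @param clusters [detect_clusters()] output.
#' @param samples sample table (`sample`, `mother`, `condition` or
#'   `group`).
#' @param chromosomes estimation chromosomes.
#' @return `data.table`: `mother`, `condition`, `chrom`, `N`, `x`.
#' @export
build_cohort_observations <- function(clusters, samples,
                                      chromosomes = c("X", "3")) {
  sdt <- data.table::as.data.table(samples)
  if (!"condition" %in% names(sdt)) sdt[, condition := group_condition(group)]
  moms <- sdt[, .(N = .N, condition = condition[1]), by = mother]
  obs <- moms[, .(chrom = chromosomes), by = .(mother, condition, N)]
  cl <- data.table::as.data.table(clusters)
  obs[, x := 0L]
  if (nrow(cl))
    obs[cl, x := i.x, on = c("mother", "chrom")]
  data.table::setcolorder(obs, c("mother", "condition", "chrom", "N", "x"))
  obs[]
}

#' Simulate cohort observations directly under the mitotic model
#'
#' Truth-level generator used for parameter recovery and likelihood-ratio
#' calibration: events are Bernoulli(alpha) per mother-chromosome, carrier
#' counts Binomial(N, beta), and a cluster is observed when the carrier
#' count reaches `min_progeny` (otherwise x is recorded as 0).
#'
#' @param n_mothers named vector: mothers per condition (`dysgenic`,
#'   `nondysgenic`).
#' @param cohort_range inclusive range cohort sizes are drawn from
#'   (uniformly).
#' @param alpha,beta named per-condition parameters (single values are
#'   recycled).
#' @param n_chrom estimation chromosomes per mother.
#' @param min_progeny detection threshold.
#' @return `data.table` of cohort observations (`mother`, `condition`,
#'   `chrom`, `N`, `x`).
#' @export
simulate_cohort_observations <- function(n_mothers = c(dysgenic = 500,
                                                       nondysgenic = 500),
                                         cohort_range = c(5, 40),
                                         alpha = c(dysgenic = 0.12,
                                                   nondysgenic = 0.12),
                                         beta = c(dysgenic = 0.78,
                                                  nondysgenic = 0.11),
                                         n_chrom = 2L, min_progeny = 4L) {
  if (length(alpha) == 1L) alpha <- c(dysgenic = unname(alpha), nondysgenic = unname(alpha))
  if (length(beta) == 1L) beta <- c(dysgenic = unname(beta), nondysgenic = unname(beta))
  out <- lapply(names(n_mothers), function(cond) {
    nm <- n_mothers[[cond]]
    if (nm == 0L) return(NULL)
    k <- nm * n_chrom
    N <- rep(sample(cohort_range[1]:cohort_range[2], nm, replace = TRUE),
             each = n_chrom)
    event <- stats::runif(k) < alpha[[cond]]
    x <- integer(k)
    x[event] <- stats::rbinom(sum(event), N[event], beta[[cond]])
    x[x < min_progeny] <- 0L
    data.table::data.table(
      mother = rep(sprintf("%s_%04d", cond, seq_len(nm)), each = n_chrom),
      condition = cond,
      chrom = rep(as.character(seq_len(n_chrom)), nm),
      N = N, x = x)
  })
  data.table::rbindlist(out)
}
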