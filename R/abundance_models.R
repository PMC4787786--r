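#' Multinomial rank-abundance log-likelihood
#'
#' The likelihood treats the observed, descending-sorted counts as a
#' multinomial draw over ranks `1..S` with `P(i)` proportional to `i^-alpha`
#' (power law) or `q (1-q)^(i-1)` (geometric), renormalized over the observed
#' ranks so both models are proper on the same support.
#'
#' @param counts Positive integer counts, rank 1 first.
#' @param model `"power_law"` or `"geometric"`.
#' @param param Model parameter.
#' @return Log-likelihood (<= 0).
#' @export
rank_loglik <- function(counts, model, param) {
  p <- rank_probabilities(model, param, length(counts))
  sum(counts * log(p))
}

#' Fit a rank-abundance model by maximum likelihood
#'
#' One-dimensional bounded numeric optimization (`alpha` in `[0, 10]`, `q` in
#' `[1e-6, 1 - 1e-6]`, tolerance 1e-8). A fit on a single rank is degenerate
#' (`P(1) = 1`): it returns `lnL = 0` with the parameter flagged
#' unidentifiable. Solutions on the search boundary are flagged.
#'
#' @param counts Positive counts sorted descending (rank 1 = most abundant).
#' @param model `"power_law"` or `"geometric"`.
#' @return List of class `ra_fit`: `model`, `parameter`, `lnL`,
#'   `identifiable`, `at_boundary`.
#' @export
fit_rank_abundance <- function(counts, model = c("power_law", "geometric")) {
  model <- match.arg(model)
  stopifnot(length(counts) >= 1, all(counts >= 1))
  if (is.unsorted(rev(counts)))
    stop("counts must be sorted in descending order (rank 1 first)")
  if (length(counts) == 1L)
    return(structure(list(model = model, parameter = NA_real_, lnL = 0,
                          identifiable = FALSE, at_boundary = FALSE),
                     class = "ra_fit"))
  bounds <- if (model == "power_law") c(0, 10) else c(1e-6, 1 - 1e-6)
  opt <- optimize(function(th) rank_loglik(counts, model, th),
                  interval = bounds, maximum = TRUE, tol = 1e-8)
  ## optimize() never evaluates the interval ends; check them explicitly so a
  ## boundary optimum (e.g. alpha-hat = 0 for equal counts) is reported exactly
  cand <- c(opt$maximum, bounds)
  ll <- vapply(cand, function(th) rank_loglik(counts, model, th), 0)
  best <- which.max(ll)
  structure(list(model = model, parameter = cand[best], lnL = ll[best],
                 identifiable = TRUE,
                 at_boundary = best > 1L ||
                   min(abs(cand[1] - bounds)) < 1e-6),
            class = "ra_fit")
}

#' Fit both rank-abundance models and pick the better one
#'
#' Both models have a single parameter, so they are compared directly by
#' maximized log-likelihood.
#'
#' @param counts Positive counts sorted descending (>= 2 ranks).
#' @return List with `power_law` and `geometric` fits, `better` (the winning
#'   model name, `"tie"` on exact equality) and `delta_lnl`
#'   (power-law minus geometric).
#' @export
compare_models <- function(counts) {
  stopifnot(length(counts) >= 2)
  pl <- fit_rank_abundance(counts, "power_law")
  ge <- fit_rank_abundance(counts, "geometric")
  d <- pl$lnL - ge$lnL
  better <- if (abs(d) < 1e-9) "tie" else if (d > 0) "power_law" else "geometric"
  list(power_law = pl, geometric = ge, better = better, delta_lnl = d)
}

.ra_counts <- function(x) sort(x[x > 0], decreasing = TRUE)

.fit_lnl <- function(counts, model) {
  if (length(counts) == 0L) return(0)
  fit_rank_abundance(counts, model)$lnL
}

## Common fit: one shared parameter; each sample's counts are evaluated under
## that parameter on its own ranks.
.common_lnl <- function(c1, c2, model) {
  bounds <- if (model == "power_law") c(0, 10) else c(1e-6, 1 - 1e-6)
  obj <- function(th) rank_loglik(c1, model, th) + rank_loglik(c2, model, th)
  opt <- optimize(obj, interval = bounds, maximum = TRUE, tol = 1e-8)
  max(vapply(c(opt$maximum, bounds), obj, 0))
}

.delta_lnl <- function(c1, c2, model) {
  (.fit_lnl(c1, model) + .fit_lnl(c2, model)) - .common_lnl(c1, c2, model)
}

#' Randomization test of a common vs separate rank-abundance distribution
#'
#' Tests whether two samples share one rank-abundance distribution. The
#' statistic is `delta lnL = (lnL1 + lnL2) - lnLb`, where `lnL1`/`lnL2` are
#' separate maximum-likelihood fits and `lnLb` fits one shared parameter to
#' both samples (each keeping its own ranks). The null distribution comes from
#' repartitioning: all individuals are pooled with their OTU labels and `n1`
#' of them are reassigned to sample 1 uniformly without replacement
#' (`scheme = "individual"`, default), or whole OTUs are reassigned by
#' swapping the two samples' counts per OTU with probability 1/2
#' (`scheme = "otu"`). The p-value uses the add-one estimator.
#'
#' @param counts Matrix or data frame, one row per OTU, two columns of counts
#'   (sample 1, sample 2).
#' @param model `"power_law"` or `"geometric"`.
#' @param n_reps Null repartitions (default 1000).
#' @param seed Integer seed.
#' @param scheme Null scheme, `"individual"` or `"otu"`.
#' @return List of class `ra_lrt`: `delta_lnl`, `n_reps`, `p_value`,
#'   `null_delta`.
#' @export
common_vs_separate_test <- function(counts, model = c("power_law", "geometric"),
                                    n_reps = 1000L, seed = 1L,
                                    scheme = c("individual", "otu")) {
  model <- match.arg(model)
  scheme <- match.arg(scheme)
  if (n_reps < 1) stop("n_reps must be >= 1")
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 2, all(counts >= 0))
  n1 <- sum(counts[, 1]); n2 <- sum(counts[, 2])
  if (n1 == 0 || n2 == 0) stop("both samples must contain individuals")
  obs <- .delta_lnl(.ra_counts(counts[, 1]), .ra_counts(counts[, 2]), model)
  set.seed(seed)
  n_otu <- nrow(counts)
  pooled <- counts[, 1] + counts[, 2]
  null_delta <- vapply(seq_len(n_reps), function(r) {
    if (scheme == "individual") {
      ## multivariate hypergeometric: draw how many of each OTU's pooled
      ## individuals land in sample 1, preserving n1 and n2
      c1 <- integer(n_otu)
      left <- n1
      remaining <- sum(pooled)
      for (i in seq_len(n_otu)) {
        remaining <- remaining - pooled[i]
        c1[i] <- rhyper(1, pooled[i], remaining, left)
        left <- left - c1[i]
      }
      c2 <- pooled - c1
    } else {
      swap <- runif(n_otu) < 0.5
      c1 <- ifelse(swap, counts[, 2], counts[, 1])
      c2 <- pooled - c1
    }
    .delta_lnl(.ra_counts(c1), .ra_counts(c2), model)
  }, 0)
  p <- (1 + sum(null_delta >= obs)) / (1 + n_reps)
  structure(list(delta_lnl = obs, n_reps = n_reps, p_value = p,
                 null_delta = null_delta, model = model, scheme = scheme),
            class = "ra_lrt")
}
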