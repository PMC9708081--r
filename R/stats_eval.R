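#' Evaluation statistics
#'
#' Improvements due to the latent spaces are scored as Bernoulli trials
#' (success = a region's rank metric did not get worse), summarised by an
#' intercept-only logistic fit: the probability estimate pB = k/n with a
#' Wald confidence interval computed on the logit scale and mapped back
#' through the logistic function. Observed success counts are compared
#' with the null binomial B(n, 0.5); p-values across regions are adjusted
#' by Benjamini-Hochberg FDR. Gene-set over-representation uses the
#' hypergeometric upper tail.
#'
#' @name stats_eval
NULL

# 97.5th normal percentile used throughout, not 1.96 rounded
.z975 <- stats::qnorm(0.975)

#' Intercept-only Bernoulli (logistic) fit
#'
#' Equivalent to `glm(cbind(k, n - k) ~ 1, family = binomial)`: the
#' estimate is `k/n` exactly; the 95% Wald interval is
#' `invlogit(logit(k/n) +- z * sqrt(1/k + 1/(n-k)))`. Degenerate cases
#' (`k` equal to 0 or `n`) are flagged and carry no interval.
#'
#' @param k number of successes
#' @param n number of trials
#' @param null_p0 null success probability for the tail test
#' @param strict use the strict tail convention (see [binomial_tail()])
#' @return An object of class `"bernoulli_fit"`: `k`, `n`, `estimate`,
#'   `ci_low`, `ci_high`, `p_null`, `degenerate`, and `q` (NA until
#'   adjusted across fits).
#' @export
fit_bernoulli <- function(k, n, null_p0 = 0.5, strict = TRUE) {
  if (n < 1) stop("n must be at least 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  p <- k / n
  degenerate <- k == 0 || k == n
  if (degenerate) {
    ci <- c(NA_real_, NA_real_)
  } else {
    se <- sqrt(1 / k + 1 / (n - k))
    ci <- stats::plogis(stats::qlogis(p) + c(-1, 1) * .z975 * se)
  }
  structure(list(k = as.integer(k), n = as.integer(n), estimate = p,
                 ci_low = ci[1], ci_high = ci[2],
                 p_null = binomial_tail(k, n, null_p0, strict = strict),
                 q = NA_real_, degenerate = degenerate),
            class = "bernoulli_fit")
}

#' @export
print.bernoulli_fit <- function(x, ...) {
  cat("Bernoulli fit: pB = ", signif(x$estimate, 3), " (", x$k, "/", x$n,
      ")", sep = "")
  if (!x$degenerate)
    cat(", 95% CI [", signif(x$ci_low, 3), ", ", signif(x$ci_high, 3), "]",
        sep = "")
  else cat(" [degenerate]")
  cat(", null tail p = ", format(signif(x$p_null, 3)), "\n", sep = "")
  invisible(x)
}

#' Exact binomial tail probability
#'
#' Probability of at least `k` successes under B(`n`, `p0`), by exact
#' summation. Under the strict convention the tail starts above the
#' observed count, `P(X >= k + 1)`; non-strict gives `P(X >= k)`.
#'
#' @param k observed success count
#' @param n number of trials
#' @param p0 null success probability, in (0, 1)
#' @param strict logical; default `TRUE`
#' @return Tail probability.
#' @export
binomial_tail <- function(k, n, p0 = 0.5, strict = TRUE) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly inside (0, 1)")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  cut <- if (strict) k else k - 1
  stats::pbinom(cut, n, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, capped at 1 and monotone in sorted order.
#'
#' @param pvals numeric vector of p-values in \[0, 1\]
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Evaluate rank improvement of latent spaces over the raw gene space
#'
#' `rank_diffs` holds, for each region (row) and ensemble member
#' (column), the difference latent-space rank minus gene-space rank of
#' the region's criterion (locality or homology); negative or zero means
#' the latent space did not do worse. The overall fit treats regions as
#' trials: success = per-region mean difference <= 0, null B(n_regions,
#' 0.5). Per-region fits treat ensemble members as trials: success =
#' member difference <= 0, null B(n_members, 0.5), with BH adjustment
#' across regions. Mean-difference CIs come from a seeded percentile
#' bootstrap over members.
#'
#' @param rank_diffs regions-by-members numeric matrix
#' @param boot_draws bootstrap draws for mean CIs, default 10000
#' @param seed bootstrap seed
#' @param strict tail convention, see [binomial_tail()]
#' @return List with `overall` ([fit_bernoulli()] result), `per_region`
#'   (list of fits with `q` filled in), and `records` (data.frame with
#'   per-region mean difference, bootstrap CI, success flag and count).
#' @export
evaluate_improvement <- function(rank_diffs, boot_draws = 10000, seed = 1,
                                 strict = TRUE) {
  stopifnot(is.matrix(rank_diffs), nrow(rank_diffs) >= 1,
            ncol(rank_diffs) >= 1)
  n_reg <- nrow(rank_diffs); n_mem <- ncol(rank_diffs)
  regions <- rownames(rank_diffs)
  if (is.null(regions)) regions <- paste0("region", seq_len(n_reg))

  mu <- rowMeans(rank_diffs)
  overall <- fit_bernoulli(sum(mu <= 0), n_reg, strict = strict)

  per_region <- lapply(seq_len(n_reg), function(i)
    fit_bernoulli(sum(rank_diffs[i, ] <= 0), n_mem, strict = strict))
  q <- bh_fdr(vapply(per_region, function(f) f$p_null, 0))
  for (i in seq_len(n_reg)) per_region[[i]]$q <- q[i]
  names(per_region) <- regions

  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  ci <- t(apply(rank_diffs, 1, function(d) {
    if (n_mem == 1) return(c(d, d))
    boots <- matrix(sample(d, n_mem * boot_draws, replace = TRUE),
                    nrow = boot_draws)
    stats::quantile(rowMeans(boots), c(0.025, 0.975), names = FALSE)
  }))

  records <- data.frame(
    region = regions,
    mean_diff = mu,
    ci_low = ci[, 1], ci_high = ci[, 2],
    success = mu <= 0,
    n_success = rowSums(rank_diffs <= 0),
    n_members = n_mem,
    pB = vapply(per_region, function(f) f$estimate, 0),
    q = q,
    row.names = NULL
  )
  list(overall = overall, per_region = per_region, records = records)
}

#' Sensorimotor vs supramodal cortex contrasts
#'
#' Tests whether maximal cross-species correlation differs by cortex type.
#' Contrast (a): ordinary least squares of each region's mean maximal
#' correlation (over ensemble members) on a supramodal indicator,
#' `df = n_regions - 2`. Contrast (b): per-member type means analysed
#' with a linear mixed model (random intercept per member), which for
#' this balanced paired design is equivalent to a paired t-test on
#' within-member differences, `df = n_members - 1`.
#'
#' @param maxcorr regions-by-members matrix of maximal correlations
#' @param type named character vector mapping each region to
#'   `"sensorimotor"` or `"supramodal"`
#' @return List of two `"regression_result"` objects (`across_regions`,
#'   `across_members`), each with `beta`, `ci_low`, `ci_high`, `t`, `df`,
#'   `p`. `beta` is the supramodal-minus-sensorimotor effect.
#' @export
cortex_type_contrast <- function(maxcorr, type) {
  stopifnot(is.matrix(maxcorr), !is.null(rownames(maxcorr)))
  type <- type[rownames(maxcorr)]
  if (any(is.na(type))) stop("every region needs a cortex type")
  if (!all(type %in% c("sensorimotor", "supramodal")))
    stop("type must be 'sensorimotor' or 'supramodal'")
  if (length(unique(type)) < 2)
    stop("both cortex types must be present")
  supra <- as.integer(type == "supramodal")

  # (a) across regions: OLS on per-region means
  region_mean <- rowMeans(maxcorr)
  if (min(table(type)) < 2)
    stop("need at least 2 regions per cortex type for the regional contrast")
  fit_a <- stats::lm(region_mean ~ supra)
  sm <- summary(fit_a)$coefficients
  ci_a <- stats::confint(fit_a)["supra", ]
  a <- structure(list(beta = unname(sm["supra", "Estimate"]),
                      ci_low = unname(ci_a[1]), ci_high = unname(ci_a[2]),
                      t = unname(sm["supra", "t value"]),
                      df = fit_a$df.residual,
                      p = unname(sm["supra", "Pr(>|t|)"])),
                 class = "regression_result")

  # (b) across members: per-member type means, random intercept per member
  n_mem <- ncol(maxcorr)
  mean_sm <- colMeans(maxcorr[type == "sensorimotor", , drop = FALSE])
  mean_su <- colMeans(maxcorr[type == "supramodal", , drop = FALSE])
  long <- data.frame(
    member = factor(rep(seq_len(n_mem), 2)),
    supra = rep(c(0, 1), each = n_mem),
    value = c(mean_sm, mean_su)
  )
  fit_b <- suppressMessages(lmerTest::lmer(value ~ supra + (1 | member),
                                           data = long))
  smb <- stats::coef(summary(fit_b))
  ci_b <- smb["supra", "Estimate"] +
    c(-1, 1) * .z975 * smb["supra", "Std. Error"]
  b <- structure(list(beta = unname(smb["supra", "Estimate"]),
                      ci_low = ci_b[1], ci_high = ci_b[2],
                      t = unname(smb["supra", "t value"]),
                      df = unname(smb["supra", "df"]),
                      p = unname(smb["supra", "Pr(>|t|)"])),
                 class = "regression_result")
  list(across_regions = a, across_members = b)
}

#' @export
print.regression_result <- function(x, ...) {
  cat("beta = ", signif(x$beta, 3), ", 95% CI [", signif(x$ci_low, 3), ", ",
      signif(x$ci_high, 3), "], t(", signif(x$df, 4), ") = ",
      signif(x$t, 4), ", p = ", format(signif(x$p, 3)), "\n", sep = "")
  invisible(x)
}

#' Hypergeometric gene-set over-representation
#'
#' For each module, tests whether the query gene set is over-represented
#' relative to the universe: `p = P(X >= overlap)` for X hypergeometric
#' with the module (intersected with the universe) as marked balls and
#' the query size as draws. Module p-values are BH-adjusted and rows
#' sorted by p.
#'
#' @param query character vector of genes (must be a subset of `universe`)
#' @param modules named list of gene vectors (e.g. from [read_gmt()])
#' @param universe character vector of background genes
#' @return data.frame with columns `module`, `module_size`, `query_size`,
#'   `universe_size`, `overlap`, `p`, `q`.
#' @export
hypergeometric_enrichment <- function(query, modules, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe)), collapse = ", "))
  rows <- lapply(names(modules), function(name) {
    mod <- intersect(unique(modules[[name]]), universe)
    ov <- length(intersect(mod, query))
    p <- stats::phyper(ov - 1, length(mod),
                       length(universe) - length(mod),
                       length(query), lower.tail = FALSE)
    data.frame(module = name, module_size = length(mod),
               query_size = length(query),
               universe_size = length(universe),
               overlap = ov, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene-set modules from a GMT file
#'
#' @param path GMT path (tab-separated: module name, description, genes)
#' @return Named list of gene vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
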