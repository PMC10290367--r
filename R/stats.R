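#' Pooled-variance two-sample Student's t test
#'
#' Independent-sample two-tailed t test with the classical pooled
#' variance, `df = n_a + n_b - 2`. Degenerate samples with zero pooled
#' variance follow the documented convention: p = 1 when the means are
#' equal, p = 0 otherwise.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
students_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  dm <- mean(a) - mean(b)
  if (sp2 <= 0) {
    return(list(t = if (dm == 0) 0 else sign(dm) * Inf, df = df,
                p = if (dm == 0) 1 else 0))
  }
  tval <- dm / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Cohen's d standardised mean difference
#'
#' `d = (mean_b - mean_a) / s_pooled` with the pooled standard deviation
#' `s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a+n_b-2))`.
#' Callable on raw samples or, via [cohens_d_summary()], on printed
#' summary statistics — the two agree exactly.
#'
#' @param a,b Numeric samples (a = reference/control arm; a positive d
#'   means arm b has the larger mean).
#' @return Cohen's d (NA if the pooled SD is zero).
#' @export
cohens_d <- function(a, b) {
  cohens_d_summary(mean(a), stats::sd(a), length(a),
                   mean(b), stats::sd(b), length(b))
}

#' @rdname cohens_d
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summary statistics.
#' @export
cohens_d_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2)
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (sp == 0) return(NA_real_)
  (mean_b - mean_a) / sp
}

#' Levene's test for equality of variances (mean-centred)
#'
#' One-way ANOVA F statistic on absolute deviations from each group mean
#' (the `center = mean` variant). Degenerate inputs whose deviations are
#' all equal give W = 0, p = 1 by convention.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @return List with `W` and `p` from the F(1, n_a + n_b - 2) reference
#'   distribution.
#' @export
levene_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  za <- abs(a - mean(a)); zb <- abs(b - mean(b))
  n1 <- length(za); n2 <- length(zb); N <- n1 + n2
  zbar <- mean(c(za, zb))
  ss_between <- n1 * (mean(za) - zbar)^2 + n2 * (mean(zb) - zbar)^2
  ss_within <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  if (ss_within <= 0) {
    if (ss_between <= 0) return(list(W = 0, p = 1))
    return(list(W = Inf, p = 0))
  }
  W <- (ss_between / 1) / (ss_within / (N - 2))
  list(W = W, p = stats::pf(W, 1, N - 2, lower.tail = FALSE))
}

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' One-sample KS distance between the empirical CDF and a normal with the
#' sample's own mean and SD (the Lilliefors variant, since the reference
#' parameters are estimated). The p value comes from a seeded Monte-Carlo
#' null table: the same statistic recomputed on `n_mc` standard-normal
#' samples of the same size.
#'
#' @param x Numeric sample, n >= 3.
#' @param n_mc Monte-Carlo replicates for the null table.
#' @param seed Optional seed for the Monte-Carlo table (RNG state is
#'   restored afterwards).
#' @return List with `D` and `p`. A constant sample is non-normal by
#'   convention (D = 1, p = 0).
#' @export
ks_normality <- function(x, n_mc = 1000, seed = NULL) {
  n <- length(x)
  stopifnot(n >= 3)
  lillie_d <- function(v) {
    s <- stats::sd(v)
    if (s == 0) return(1)
    z <- sort((v - mean(v)) / s)
    fi <- stats::pnorm(z)
    max(seq_len(n) / n - fi, fi - (seq_len(n) - 1) / n)
  }
  D <- lillie_d(x)
  if (D >= 1) return(list(D = 1, p = 0))
  d_null <- with_seed(seed, vapply(seq_len(n_mc), function(i)
    lillie_d(stats::rnorm(n)), numeric(1)))
  list(D = D, p = (1 + sum(d_null >= D)) / (n_mc + 1))
}

# Exact null distributions of the rank sum are memoised per (ranks, n_a)
# so repeated 6+6 tests (simulation studies) stay cheap.
.mw_cache <- new.env(parent = emptyenv())

mw_exact_p <- function(ranks, n_a, u_obs) {
  N <- length(ranks)
  key <- paste(c(n_a, signif(sort(ranks), 12)), collapse = ",")
  dist_u <- .mw_cache[[key]]
  if (is.null(dist_u)) {
    combs <- utils::combn(N, n_a)
    rsums <- colSums(matrix(sort(ranks)[combs], nrow = n_a))
    dist_u <- rsums - n_a * (n_a + 1) / 2
    .mw_cache[[key]] <- dist_u
  }
  p_le <- mean(dist_u <= u_obs + 1e-9)
  p_ge <- mean(dist_u >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

#' Mann-Whitney U test with exact small-sample p
#'
#' U statistic of the first sample from midranks. For total sample sizes
#' up to `exact_max` (default 14, covering the 6 + 6 study regime) the
#' two-tailed p is computed exactly by full enumeration of all
#' `choose(n_a + n_b, n_a)` group labelings of the observed ranks — valid
#' with ties, since the enumeration permutes the actual midranks.
#' Larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Numeric samples, each n >= 1.
#' @param exact_max Largest `n_a + n_b` for which full enumeration is
#'   used.
#' @return List with `U` (of sample `a`), `p` (two-tailed), `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 14) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 1, nb >= 1)
  N <- na + nb
  r <- rank(c(a, b))      # midranks for ties
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (N <= exact_max) {
    p <- mw_exact_p(r, na, U)
    return(list(U = U, p = p, method = "exact"))
  }
  mu <- na * nb / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(na * nb / 12 * ((N + 1) - tie_term))
  if (sigma == 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

#' Parametric-vs-nonparametric test selection
#'
#' Mirrors the reporting rule of two-arm preclinical studies: Student's t
#' when both samples pass KS (Lilliefors) normality and Levene variance
#' homogeneity at `normality_alpha`, otherwise Mann-Whitney U. The
#' triggering diagnostic is attached.
#'
#' @param a,b Numeric samples.
#' @param normality_alpha Screening level; default 0.05.
#' @param seed Seed for the KS Monte-Carlo table.
#' @return `"t"` or `"mann_whitney"`, with attribute `diagnostics`.
#' @export
choose_test <- function(a, b, normality_alpha = 0.05, seed = NULL) {
  ks_a <- ks_normality(a, seed = seed)
  ks_b <- ks_normality(b, seed = if (is.null(seed)) NULL else seed + 1)
  lev <- levene_test(a, b)
  diag <- c(ks_p_a = ks_a$p, ks_p_b = ks_b$p, levene_p = lev$p)
  ok <- all(diag >= normality_alpha)
  structure(if (ok) "t" else "mann_whitney", diagnostics = diag)
}
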