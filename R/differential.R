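## Differential STARR-seq activity between conditions: median-of-ratios
## size factors, input-coupled per-peak normalization factors, and a
## negative-binomial Wald test whose dispersion model accounts for the
## Poisson sampling noise that the input-derived normalization factors
## carry into the offsets.

#' Median-of-ratios size factors
#'
#' For each library, the median over rows of `count_ij / geometric_mean_i`,
#' computed on rows where every library has a positive count.
#'
#' @param mat non-negative count matrix, rows = peaks, columns = libraries.
#' @param pseudo_reference if `TRUE`, fall back to adding 0.5 to all counts
#'   when no row is all-positive.
#' @return positive numeric vector of per-library factors.
#' @export
size_factors <- function(mat, pseudo_reference = FALSE) {
  mat <- as.matrix(mat)
  lg <- rowMeans(log(mat))
  ok <- is.finite(lg)
  if (!any(ok)) {
    if (!pseudo_reference) {
      stop("no row with all-positive counts; consider pseudo_reference = TRUE")
    }
    mat <- mat + 0.5
    lg <- rowMeans(log(mat))
    ok <- rep(TRUE, nrow(mat))
  }
  sf <- apply(mat, 2, function(col) exp(stats::median((log(col) - lg)[ok])))
  stopifnot(all(sf > 0))
  sf
}

#' Per-peak, per-library normalization factors
#'
#' `NF_ij = (sf_starr_j / sf_input_j) * max(input_ij, 1)`, where `input_ij`
#' is the per-peak maximum of scaled input and unique STARR reads, floored
#' at 1 to stay positive; each row is then divided by its geometric mean so
#' rows have geometric mean 1 across libraries.
#'
#' @param sf_starr,sf_input per-library size factors of total STARR and
#'   scaled input counts.
#' @param input_mat per-peak x per-library matrix `max(m, u)`.
#' @return matrix of normalization factors, all entries positive, row
#'   geometric means 1.
#' @export
normalization_factors <- function(sf_starr, sf_input, input_mat) {
  stopifnot(all(sf_starr > 0), all(sf_input > 0), all(input_mat >= 0))
  raw <- sweep(pmax(as.matrix(input_mat), 1), 2, sf_starr / sf_input, "*")
  raw / exp(rowMeans(log(raw)))
}

#' Build the differential input matrices from a long counts table
#'
#' @param counts,libraries as in [enrichment_table()].
#' @return list of matrices `k`, `u`, `r`, `m`, `input` (= `max(m, u)`),
#'   plus the library metadata ordered as the columns and the condition
#'   factor.
#' @export
count_matrices <- function(counts, libraries) {
  libs <- libraries[order(libraries$condition, libraries$replicate), ]
  ids <- unique(counts$region_id)
  pick <- function(col) {
    m <- vapply(libs$library, function(l) {
      sub <- counts[counts$library == l, ]
      sub[[col]][match(ids, sub$region_id)]
    }, numeric(length(ids)))
    rownames(m) <- ids
    m
  }
  k <- pick("k"); u <- pick("u"); r <- pick("r")
  m <- vapply(seq_len(nrow(libs)), function(j) {
    scale_input_counts_vec(r[, j], libs$starr_total[j], libs$input_total[j])
  }, numeric(length(ids)))
  dimnames(m) <- dimnames(k)
  list(k = k, u = u, r = r, m = m, input = pmax(m, u), libraries = libs,
       condition = factor(libs$condition))
}

## NB GLM with log link and fixed dispersion, fitted by IRLS.
nb_irls <- function(k, X, off, phi, maxit = 30) {
  beta <- c(log(mean(k / exp(off)) + 0.1), rep(0, ncol(X) - 1))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + off
    mu <- pmin(exp(eta), 1e8)
    W <- mu / (1 + phi * mu)
    z <- eta - off + (k - mu) / mu
    XtW <- t(X * W)
    bn <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(bn)) return(NULL)
    if (max(abs(bn - beta)) < 1e-8) { beta <- drop(bn); break }
    beta <- drop(bn)
  }
  mu <- pmin(exp(drop(X %*% beta) + off), 1e8)
  list(beta = beta, mu = mu, W = mu / (1 + phi * mu))
}

## Cox-Reid adjusted profile log-likelihood of the dispersion for one peak.
nb_apl <- function(k, X, off, phi) {
  f <- nb_irls(k, X, off, phi)
  if (is.null(f) || any(!is.finite(f$mu))) return(-Inf)
  ll <- sum(stats::dnbinom(k, size = 1 / phi, mu = f$mu, log = TRUE))
  d <- determinant(t(X * f$W) %*% X, logarithm = TRUE)$modulus
  as.numeric(ll - 0.5 * d)
}

#' Fit the shared dispersion model
#'
#' Per-peak dispersion is modeled as `phi_i = phi0 + c * mean_j(1 / r_ij)`:
#' a residual component shared across peaks plus a term proportional to the
#' delta-method variance that Poisson noise in the input-derived
#' normalization factors contributes to the log-scale offsets. Both
#' hyperparameters are fitted by maximizing the summed Cox-Reid adjusted
#' profile likelihood over a subsample of peaks. With few libraries a
#' peak-by-peak dispersion cannot be estimated stably; tying the dispersion
#' to observable input coverage keeps the Wald test calibrated.
#'
#' @param k count matrix (total STARR reads).
#' @param X design matrix.
#' @param off offset matrix (`log NF`).
#' @param offset_noise per-peak mean of `1 / max(r, 1)`, or zeros when no
#'   input counts back the offsets.
#' @param n_fit subsample size for the pooled fit.
#' @return list `phi0`, `c`, `phi` (per-peak vector).
#' @export
fit_dispersion <- function(k, X, off, offset_noise, n_fit = 500) {
  n <- nrow(k)
  sub <- if (n > n_fit) sample(n, n_fit) else seq_len(n)
  has_noise <- any(offset_noise > 0)
  obj <- function(par) {
    phi0 <- exp(par[1])
    cc <- if (has_noise) exp(par[2]) else 0
    -sum(vapply(sub, function(i) {
      nb_apl(k[i, ], X, off[i, ], phi0 + cc * offset_noise[i])
    }, numeric(1)))
  }
  if (has_noise) {
    fit <- stats::optim(c(log(1e-4), log(1)), obj, method = "Nelder-Mead",
                        control = list(maxit = 80, reltol = 1e-4))
    phi0 <- exp(fit$par[1]); cc <- exp(fit$par[2])
  } else {
    fit <- stats::optimize(function(p) obj(c(p, 0)), c(log(1e-8), log(30)))
    phi0 <- exp(fit$minimum); cc <- 0
  }
  list(phi0 = phi0, c = cc,
       phi = pmax(phi0 + cc * offset_noise, 1e-8))
}

#' Negative-binomial Wald test for differential activity
#'
#' Per peak, fits an NB regression of total STARR counts on condition with
#' log link and offset `log NF_ij`, using the shared dispersion model of
#' [fit_dispersion()], and reports the two-sided Wald test on the condition
#' coefficient (second condition vs first, i.e. SL vs 2iL under the default
#' labels). P values are BH-adjusted across peaks. Peaks whose fit fails
#' are flagged and reported with `p = 1`.
#'
#' @param k matrix of total STARR counts (rows peaks, columns libraries).
#' @param NF normalization-factor matrix from [normalization_factors()].
#' @param condition factor of column conditions (2 levels).
#' @param r optional matrix of raw input reads backing the normalization
#'   factors; enables the offset-noise dispersion component.
#' @param dispersion optional fixed per-peak dispersion vector (bypasses
#'   [fit_dispersion()]).
#' @return data.frame: `region_id`, `baseMean`, `log2fc`, `se`, `p`,
#'   `p_adj`, `converged`.
#' @export
nb_wald_test <- function(k, NF, condition, r = NULL, dispersion = NULL) {
  k <- as.matrix(k)
  condition <- factor(condition)
  stopifnot(nlevels(condition) == 2, ncol(k) == length(condition),
            all(table(condition) >= 2), all(NF > 0))
  X <- cbind(1, as.numeric(condition == levels(condition)[2]))
  off <- log(as.matrix(NF))
  n <- nrow(k)
  offset_noise <- if (is.null(r)) rep(0, n) else rowMeans(1 / pmax(as.matrix(r), 1))
  if (is.null(dispersion)) {
    disp <- fit_dispersion(k, X, off, offset_noise)
    phi <- disp$phi
  } else {
    phi <- rep(dispersion, length.out = n)
  }
  res <- t(vapply(seq_len(n), function(i) {
    f <- nb_irls(k[i, ], X, off[i, ], phi[i])
    if (is.null(f) || any(!is.finite(f$beta))) return(c(NA, NA, NA))
    cv <- tryCatch(solve(t(X * f$W) %*% X), error = function(e) NULL)
    if (is.null(cv) || !is.finite(cv[2, 2]) || cv[2, 2] <= 0) {
      return(c(f$beta[2] / log(2), NA, NA))
    }
    se <- sqrt(cv[2, 2])
    c(f$beta[2] / log(2), se / log(2), f$beta[2] / se)
  }, numeric(3)))
  p <- 2 * stats::pnorm(-abs(res[, 3]))
  failed <- is.na(p)
  p[failed] <- 1
  out <- data.frame(region_id = if (is.null(rownames(k))) as.character(seq_len(n)) else rownames(k),
                    baseMean = rowMeans(sweep(k, 2, exp(colMeans(off)), "/")),
                    log2fc = res[, 1], se = res[, 2], p = p,
                    p_adj = bh_adjust(p),
                    converged = !failed, stringsAsFactors = FALSE)
  attr(out, "dispersion") <- phi
  out
}

#' Flag differential peaks
#'
#' The call rule: absolute fold change at least `fc_threshold` and p value
#' below `p_threshold` (unadjusted Wald p by default; set
#' `adjusted = TRUE` for the BH-adjusted rule).
#'
#' @param records output of [nb_wald_test()].
#' @param fc_threshold minimum absolute fold change (natural scale).
#' @param p_threshold p value cutoff.
#' @param adjusted use `p_adj` instead of `p`.
#' @param labels direction labels for (first, second) condition level.
#' @return the records with `call` added: `"up_SL"`, `"up_2iL"` (direction
#'   labels follow the factor levels used in the test) or `"ns"`.
#' @export
flag_differential <- function(records, fc_threshold = 2.5,
                              p_threshold = 0.05, adjusted = FALSE,
                              labels = c("up_2iL", "up_SL")) {
  pv <- if (adjusted) records$p_adj else records$p
  hit <- !is.na(records$log2fc) & abs(records$log2fc) >= log2(fc_threshold) &
    pv < p_threshold
  records$call <- ifelse(!hit, "ns",
                         ifelse(records$log2fc > 0, labels[2], labels[1]))
  records
}

#' Run the full differential analysis from a long counts table
#'
#' Convenience wrapper: builds matrices, size factors on total STARR and
#' scaled input counts, normalization factors, the NB Wald test, and the
#' differential call.
#'
#' @param counts,libraries as in [enrichment_table()].
#' @param fc_threshold,p_threshold,adjusted as in [flag_differential()].
#' @return list `records`, `NF`, `sf_starr`, `sf_input`, `matrices`.
#' @export
differential_analysis <- function(counts, libraries, fc_threshold = 2.5,
                                  p_threshold = 0.05, adjusted = FALSE) {
  mats <- count_matrices(counts, libraries)
  sf_starr <- size_factors(mats$k, pseudo_reference = TRUE)
  sf_input <- size_factors(pmax(mats$m, 1), pseudo_reference = TRUE)
  NF <- normalization_factors(sf_starr, sf_input, mats$input)
  rec <- nb_wald_test(mats$k, NF, mats$condition, r = mats$r)
  rec <- flag_differential(rec, fc_threshold, p_threshold, adjusted,
                           labels = paste0("up_", levels(mats$condition)))
  list(records = rec, NF = NF, sf_starr = sf_starr, sf_input = sf_input,
       matrices = mats)
}
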