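# Admixture-aware allele-frequency selection scan: site filtering,
# per-component allele-frequency MLEs under a binomial model, a nested
# likelihood-ratio statistic per (site, component), thresholding, and
# per-population allele-frequency profiles.
#
# The model: individual i carries dosage g_i ~ Binomial(2, p_i) with
# p_i = sum_k Q_ik F_k, where Q (individuals x K) holds known ancestry
# proportions and F (K) the component allele frequencies.  The scan
# statistic contrasts, for a focal component k, the model with F_k free and
# all other components tied to one shared frequency against the model with
# one shared frequency for everyone: LRT = 2 (logL1 - logL0), compared to a
# chi-squared distribution with 1 df.  It asks the same question as
# tree-covariance selection models — is this site's frequency in one
# ancestry component inconsistent with a genome-wide profile — with a
# deliberately simpler null.

#' Genotype container for the selection scan
#'
#' @param G Integer matrix, sites x individuals, dosages in
#'   `{0, 1, 2, NA}`.
#' @param sites Optional tibble of site metadata (one row per row of `G`).
#' @param samples Optional tibble of individual metadata with at least a
#'   `population` column when profiles are wanted.
#' @return A list of class `sv_genotypes` with elements `G`, `sites`,
#'   `samples`.
#' @export
sv_genotypes <- function(G, sites = NULL, samples = NULL) {
  G <- as.matrix(G)
  stopifnot(all(G %in% c(0L, 1L, 2L, NA)))
  if (is.null(sites)) {
    sites <- tibble(site = rownames(G) %||% paste0("site", seq_len(nrow(G))))
  }
  if (is.null(samples)) {
    samples <- tibble(sample = colnames(G) %||%
                        paste0("ind", seq_len(ncol(G))))
  }
  stopifnot(nrow(sites) == nrow(G), nrow(samples) == ncol(G))
  structure(list(G = G, sites = as_tibble(sites),
                 samples = as_tibble(samples)),
            class = "sv_genotypes")
}

#' Read an ancestry-proportion (Q) matrix from TSV
#'
#' @param path TSV with one row per individual; a first `sample` column is
#'   used as row identifier when present, remaining numeric columns are the
#'   K components.
#' @return A numeric matrix individuals x K with rows summing to 1.
#' @export
read_q_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if ("sample" %in% names(df)) {
    ids <- df$sample
    df <- df[setdiff(names(df), "sample")]
  } else {
    ids <- paste0("ind", seq_len(nrow(df)))
  }
  Q <- as.matrix(df)
  rownames(Q) <- ids
  validate_q(Q)
  Q
}

validate_q <- function(Q, tol = 1e-9) {
  stopifnot(is.numeric(Q), ncol(Q) >= 1L,
            all(Q >= -tol), all(Q <= 1 + tol),
            all(abs(rowSums(Q) - 1) <= 1e-6))
  invisible(Q)
}

#' Read a dosage TSV into a genotype container
#'
#' @param path TSV with one row per site; a first `site` column is used as
#'   the site identifier when present, remaining columns are per-individual
#'   dosages in `{0, 1, 2}` with empty/NA for missing.
#' @return An [sv_genotypes()] object.
#' @export
read_dosage_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if ("site" %in% names(df)) {
    sites <- tibble(site = as.character(df$site))
    df <- df[setdiff(names(df), "site")]
  } else {
    sites <- tibble(site = paste0("site", seq_len(nrow(df))))
  }
  G <- as.matrix(df)
  mode(G) <- "integer"
  rownames(G) <- sites$site
  sv_genotypes(G, sites = sites, samples = tibble(sample = colnames(G)))
}

#' Read a multi-sample genotype VCF into dosages
#'
#' Extracts the GT field of every record and codes the number of alternate
#' alleles per individual (0, 1, 2; anything containing `.` is `NA`).
#'
#' @param path VCF file path.
#' @return An [sv_genotypes()] object; `sites` carries `chrom`, `pos`.
#' @export
read_genotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || grepl(".", g, fixed = TRUE)) return(NA_integer_)
    sum(as.integer(strsplit(g, "[/|]")[[1L]]) > 0L)
  })
  fix <- vcfR::getFIX(vcf)
  sv_genotypes(dose,
               sites = tibble(site = paste(fix[, "CHROM"], fix[, "POS"],
                                           sep = ":"),
                              chrom = fix[, "CHROM"],
                              pos = as.integer(fix[, "POS"])),
               samples = tibble(sample = colnames(gt)))
}

#' Filter scan sites on missingness and minor allele frequency
#'
#' Keeps sites with at most `max_missing` missing genotypes (default 0 —
#' no missing genotypes) and minor allele frequency at least `maf`
#' (inclusive; default 0.05, so 1 alternate allele among 10 diploids is
#' kept).
#'
#' @param geno An [sv_genotypes()] object.
#' @param maf Minimum minor allele frequency (inclusive).
#' @param max_missing Maximum number of missing genotypes per site.
#' @return The filtered `sv_genotypes` object.
#' @export
site_filters <- function(geno, maf = 0.05, max_missing = 0L) {
  stopifnot(inherits(geno, "sv_genotypes"))
  G <- geno$G
  n_miss <- rowSums(is.na(G))
  p <- rowSums(G, na.rm = TRUE) / (2 * rowSums(!is.na(G)))
  m <- pmin(p, 1 - p)
  keep <- n_miss <= max_missing & !is.na(m) & m >= maf
  sv_genotypes(G[keep, , drop = FALSE], geno$sites[keep, , drop = FALSE],
               geno$samples)
}

# binomial log-likelihood of dosages g under per-individual alt frequency p
binom_loglik <- function(g, p) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(g * log(p) + (2 - g) * log(1 - p))
}

#' Maximum-likelihood component allele frequencies at one site
#'
#' Maximises the binomial log-likelihood
#' `sum_i [g_i log p_i + (2 - g_i) log(1 - p_i)]` with
#' `p_i = sum_k Q_ik F_k` over `F` in `[0,1]^K`, via EM-style
#' multiplicative updates (each allele copy's ancestry is the latent
#' variable) with deterministic initialisation at the pooled frequency.
#'
#' @param g Integer dosages (no missing values).
#' @param Q Ancestry-proportion matrix, individuals x K.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Iteration cap (default 10000).
#' @return Numeric vector `F` of length K with a `loglik` attribute.
#' @export
fit_component_frequencies <- function(g, Q, tol = 1e-8, max_iter = 10000L) {
  validate_q(Q)
  stopifnot(length(g) == nrow(Q), !anyNA(g))
  K <- ncol(Q)
  pooled <- sum(g) / (2 * length(g))
  if (pooled == 0) return(structure(rep(0, K), loglik = 0))
  if (pooled == 1) return(structure(rep(1, K), loglik = 0))
  eps <- 1e-9
  f <- rep(min(max(pooled, eps), 1 - eps), K)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    p <- pmin(pmax(drop(Q %*% f), eps), 1 - eps)
    # E-step responsibilities, M-step closed form per component
    num <- colSums((g / p) * Q) * f
    den <- num + colSums(((2 - g) / (1 - p)) * Q) * (1 - f)
    f <- ifelse(den > 0, num / den, f)
    f <- pmin(pmax(f, 0), 1)
    ll <- binom_loglik(g, drop(Q %*% f))
    if (abs(ll - ll_old) < tol) {
      return(structure(f, loglik = ll))
    }
    ll_old <- ll
  }
  stop("frequency fit did not converge within ", max_iter, " iterations")
}

#' Likelihood-ratio selection statistic for one site and focal component
#'
#' Compares the model where the focal component's frequency is free and all
#' remaining components share one frequency against the model with a single
#' shared frequency for all components. Under neutrality the statistic is
#' asymptotically chi-squared with 1 df.
#'
#' @param g Integer dosages (no missing values).
#' @param Q Ancestry-proportion matrix, individuals x K.
#' @param k Focal component (column index of `Q`).
#' @param ... Passed to [fit_component_frequencies()].
#' @return A one-row tibble `component`, `f_focal`, `f_other`, `lrt`,
#'   `p_value`; all `NA` when component `k` has zero total weight.
#' @export
scan_statistic <- function(g, Q, k, ...) {
  validate_q(Q)
  if (sum(Q[, k]) == 0) {
    return(tibble(component = k, f_focal = NA_real_, f_other = NA_real_,
                  lrt = NA_real_, p_value = NA_real_))
  }
  # null: one shared frequency -> pooled-frequency MLE in closed form
  f0 <- sum(g) / (2 * length(g))
  ll0 <- binom_loglik(g, rep(f0, length(g)))
  # alternative: focal component free, all others tied
  Q2 <- cbind(Q[, k], 1 - Q[, k])
  f1 <- fit_component_frequencies(g, Q2, ...)
  ll1 <- max(attr(f1, "loglik"), ll0) # nested: never below the null
  lrt <- 2 * (ll1 - ll0)
  tibble(component = k, f_focal = f1[1L], f_other = f1[2L], lrt = lrt,
         p_value = pchisq(lrt, df = 1, lower.tail = FALSE))
}

#' Bonferroni significance threshold
#'
#' @param n_tests Number of tests (must be at least 1).
#' @param alpha Nominal family-wise significance level (default 0.05).
#' @return `alpha / n_tests` (e.g. 1.67e-7 for 299,115 tests at 0.05).
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1) {
    stop("n_tests must be a single count >= 1")
  }
  alpha / n_tests
}

#' Run the selection scan over all sites and components
#'
#' Fits the full K-component frequency vector per site and the
#' per-component likelihood-ratio statistic, then flags hits at the strict
#' Bonferroni threshold (`alpha / n_tests`, where `n_tests` counts
#' site-component pairs unless overridden) and at the fixed relaxed
#' threshold.
#'
#' @param geno An [sv_genotypes()] object that passed [site_filters()].
#' @param Q Ancestry-proportion matrix, individuals x K.
#' @param components Components to test (default all).
#' @param alpha Family-wise level for the strict threshold (default 0.05).
#' @param relaxed Fixed relaxed p-value cutoff (default 1e-4).
#' @param n_tests Test count for the Bonferroni correction; defaults to
#'   sites x components tested here.
#' @return An object of class `sv_scan`: a list with `results` (tibble:
#'   `site`, `component`, `f_focal`, `f_other`, `lrt`, `p_value`,
#'   `strict`, `relaxed`), `F_hat` (sites x K matrix of component
#'   frequencies), `n_tests`, `strict_threshold`, `relaxed_threshold`.
#' @export
selection_scan <- function(geno, Q, components = seq_len(ncol(Q)),
                           alpha = 0.05, relaxed = 1e-4, n_tests = NULL) {
  stopifnot(inherits(geno, "sv_genotypes"))
  validate_q(Q)
  G <- geno$G
  if (anyNA(G)) stop("scan requires no missing genotypes; run site_filters()")
  n_sites <- nrow(G)
  if (is.null(n_tests)) n_tests <- n_sites * length(components)
  strict_threshold <- bonferroni_threshold(n_tests, alpha)
  F_hat <- matrix(NA_real_, n_sites, ncol(Q))
  res <- vector("list", n_sites)
  site_ids <- geno$sites$site %||% paste0("site", seq_len(n_sites))
  for (s in seq_len(n_sites)) {
    g <- G[s, ]
    F_hat[s, ] <- fit_component_frequencies(g, Q)
    rows <- bind_rows(lapply(components, function(k) scan_statistic(g, Q, k)))
    rows$site <- site_ids[s]
    res[[s]] <- rows
  }
  results <- bind_rows(res) %>%
    mutate(strict = !is.na(.data$p_value) & .data$p_value <= strict_threshold,
           relaxed = !is.na(.data$p_value) & .data$p_value <= relaxed) %>%
    select("site", "component", "f_focal", "f_other", "lrt", "p_value",
           "strict", "relaxed")
  structure(list(results = results, F_hat = F_hat, n_tests = n_tests,
                 strict_threshold = strict_threshold,
                 relaxed_threshold = relaxed, sites = geno$sites),
            class = "sv_scan")
}

#' @export
print.sv_scan <- function(x, ...) {
  cat("Admixture-component selection scan\n")
  cat("  sites x components tested:", x$n_tests, "\n")
  cat("  strict (Bonferroni) threshold:",
      format(x$strict_threshold, digits = 3), "\n")
  cat("  relaxed threshold:", format(x$relaxed_threshold, digits = 3), "\n")
  cat("  strict hits:", sum(x$results$strict, na.rm = TRUE),
      " relaxed hits:", sum(x$results$relaxed, na.rm = TRUE), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a selection scan
#'
#' @param x An `sv_scan` object.
#' @param ... Unused.
#' @return The per-(site, component) results tibble.
#' @export
tidy.sv_scan <- function(x, ...) x$results

#' One-row summary of a selection scan
#'
#' @param x An `sv_scan` object.
#' @param ... Unused.
#' @return A one-row tibble with test counts, thresholds and hit counts.
#' @export
glance.sv_scan <- function(x, ...) {
  tibble(n_tests = x$n_tests,
         strict_threshold = x$strict_threshold,
         relaxed_threshold = x$relaxed_threshold,
         n_strict = sum(x$results$strict, na.rm = TRUE),
         n_relaxed = sum(x$results$relaxed, na.rm = TRUE))
}

#' Per-population alternate-allele frequency profiles
#'
#' @param geno An [sv_genotypes()] object whose `samples` tibble has a
#'   `population` column (or supply `labels`).
#' @param labels Optional character vector of population labels, one per
#'   individual.
#' @return A tibble `site`, `population`, `n`, `alt_freq` where
#'   `alt_freq = sum(dosage) / (2 n)` over non-missing genotypes.
#' @export
allele_frequency_profiles <- function(geno, labels = NULL) {
  stopifnot(inherits(geno, "sv_genotypes"))
  labels <- labels %||% geno$samples$population
  if (is.null(labels)) stop("no population labels available")
  stopifnot(length(labels) == ncol(geno$G))
  site_ids <- geno$sites$site %||% paste0("site", seq_len(nrow(geno$G)))
  out <- lapply(unique(labels), function(pop) {
    Gp <- geno$G[, labels == pop, drop = FALSE]
    n_ok <- rowSums(!is.na(Gp))
    tibble(site = site_ids, population = pop, n = unname(n_ok),
           alt_freq = unname(ifelse(n_ok > 0,
                                    rowSums(Gp, na.rm = TRUE) / (2 * n_ok),
                                    NA_real_)))
  })
  bind_rows(out)
}
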