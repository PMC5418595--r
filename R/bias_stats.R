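# Promoter-incorporation bias statistics: chi-squared goodness of fit per gene
# slot against the random-assembly null, with an exact multinomial fallback
# for small expected counts, and Fisher's exact test for category enrichment
# among producer strains.

#' Chi-squared test for promoter-incorporation bias
#'
#' Compares the observed promoter-category counts at one gene slot against the
#' distribution expected by chance (the slot's candidate-category fractions,
#' see [null_category_distribution()]). The statistic is
#' `sum((O - E)^2 / E)` over categories with nonzero null mass, with
#' `dof = (#nonzero-mass categories) - 1` and an upper-tail chi-squared
#' p-value. When any expected count falls below `exact_threshold` (default 5,
#' the standard rule of thumb), the p-value is additionally computed by exact
#' multinomial enumeration (or Monte Carlo when enumeration is infeasible) and
#' that method becomes authoritative.
#'
#' @param counts A `promoter_counts` table ([tabulate_promoters()]), or a
#'   named numeric vector of category counts.
#' @param design A [library_design()] (needed to derive the null; ignored if
#'   `null` is supplied).
#' @param gene Gene slot to test.
#' @param stage Optional stage filter applied to `counts`.
#' @param null Optional named probability vector over categories (overrides
#'   the design-derived null).
#' @param exact_threshold Expected-count threshold triggering the exact method.
#' @param exact_B Monte Carlo replicates when enumeration is infeasible.
#' @param seed Seed for the Monte Carlo fallback.
#' @return An object of class `bias_test`: `gene`, `stage`, `statistic`,
#'   `dof`, `p_value`, `p_chi2`, `p_exact`, `method` (`"chi2"` or
#'   `"exact_multinomial"`), `observed`, `expected`.
#' @export
chi2_bias_test <- function(counts, design = NULL, gene = NULL, stage = NULL,
                           null = NULL, exact_threshold = 5, exact_B = 1e4,
                           seed = 1L) {
  if (inherits(counts, "promoter_counts")) {
    stopifnot(!is.null(gene))
    x <- counts[counts$gene == gene, , drop = FALSE]
    if (!is.null(stage)) x <- x[x$stage == stage, , drop = FALSE]
    obs <- tapply(x$count, factor(x$category, levels = PROMOTER_CATEGORIES),
                  sum, default = 0)
    obs <- setNames(as.numeric(obs), PROMOTER_CATEGORIES)
  } else {
    obs <- counts
    stopifnot(!is.null(names(obs)))
  }
  if (is.null(null)) {
    stopifnot(inherits(design, "library_design"), !is.null(gene))
    null <- null_category_distribution(design, gene)
  }
  null <- null[names(obs)]
  if (anyNA(null)) stop("null distribution missing categories: ",
                        paste(names(obs)[is.na(null)], collapse = ", "))
  n <- sum(obs)
  if (n <= 0) stop("all-zero observed table")
  keep <- null > 0
  if (any(obs[!keep] > 0))
    stop("observed counts in categories with zero null mass: ",
         paste(names(obs)[!keep & obs > 0], collapse = ", "))
  o <- obs[keep]
  p <- null[keep] / sum(null[keep])
  e <- n * p
  stat <- sum((o - e)^2 / e)
  dof <- length(o) - 1L
  p_chi2 <- pchisq(stat, df = dof, lower.tail = FALSE)
  p_exact <- NA_real_
  method <- "chi2"
  if (any(e < exact_threshold)) {
    p_exact <- exact_multinomial_p(o, p, B = exact_B, seed = seed)
    method <- "exact_multinomial"
  }
  structure(list(gene = gene %||% NA_character_, stage = stage %||% NA_character_,
                 statistic = stat, dof = dof,
                 p_value = if (method == "chi2") p_chi2 else p_exact,
                 p_chi2 = p_chi2, p_exact = p_exact, method = method,
                 observed = o, expected = e),
            class = "bias_test")
}

#' @export
print.bias_test <- function(x, ...) {
  cat(sprintf("Incorporation bias test (%s)%s%s\n", x$method,
              if (!is.na(x$gene)) paste0(" gene=", x$gene) else "",
              if (!is.na(x$stage)) paste0(" stage=", x$stage) else ""))
  cat(sprintf("  X-squared = %.4g, dof = %d, p = %.4g\n",
              x$statistic, x$dof, x$p_value))
  print(rbind(observed = x$observed, expected = round(x$expected, 2)))
  invisible(x)
}

# Exact multinomial goodness-of-fit p-value, ordering outcomes by the
# chi-squared statistic: p = P(stat(X) >= stat(obs)) under the null.
# Full enumeration of compositions when feasible, else Monte Carlo.
exact_multinomial_p <- function(obs, p, B = 1e4, seed = 1L,
                                enum_limit = 5e5) {
  n <- sum(obs)
  k <- length(obs)
  e <- n * p
  stat_obs <- sum((obs - e)^2 / e)
  n_comp <- choose(n + k - 1, k - 1)
  if (n_comp <= enum_limit) {
    comps <- compositions(n, k)
    stat <- colSums((t(comps) - e)^2 / e)
    logp <- lgamma(n + 1) - rowSums(lgamma(comps + 1)) +
      as.vector(comps %*% log(p))
    return(sum(exp(logp[stat >= stat_obs - 1e-9])))
  }
  with_seed(seed, {
    x <- rmultinom(B, n, p)
    stat <- colSums((x - e)^2 / e)
    mean(stat >= stat_obs - 1e-9)
  })
}

# all nonnegative integer k-vectors summing to n (rows)
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1))
  sub <- lapply(0:n, function(i) cbind(i, compositions(n - i, k - 1L)))
  out <- do.call(rbind, sub)
  dimnames(out) <- NULL
  out
}

#' Fisher's exact test for category enrichment
#'
#' Two-sided Fisher's exact test on a 2x2 table
#' `[[a, b], [c, d]] = [[producers with category, producers without],
#' [reference with, reference without]]`, computed by direct hypergeometric
#' enumeration: with margins fixed, every table at least as extreme (point
#' probability not exceeding the observed one, within a 1e-7 relative
#' tolerance) contributes its probability. The odds ratio is the sample
#' `a*d / (b*c)`, `Inf` when `b*c = 0` (and `NaN` for `0/0`).
#'
#' @param table A 2x2 matrix of nonnegative integer counts, or `a` as the
#'   first cell with `b`, `c`, `d` given separately.
#' @param b,c,d Remaining cells when `table` is given as a scalar.
#' @param gene,category Optional labels carried through to the result.
#' @return An object of class `enrichment_test`: `gene`, `category`, `table`,
#'   `p_value`, `odds_ratio`.
#' @export
fisher_enrichment_test <- function(table, b = NULL, c = NULL, d = NULL,
                                   gene = NULL, category = NULL) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == 2))
    tab <- table
  } else {
    tab <- matrix(c(table, c, b, d), nrow = 2)
  }
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table must contain nonnegative integers")
  a <- tab[1, 1]; b_ <- tab[1, 2]; c_ <- tab[2, 1]; d_ <- tab[2, 2]
  r1 <- a + b_                       # producers
  c1 <- a + c_; c2 <- b_ + d_        # with / without category
  lo <- max(0, r1 - c2); hi <- min(r1, c1)
  dens <- stats::dhyper(lo:hi, c1, c2, r1)
  p_obs <- stats::dhyper(a, c1, c2, r1)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  or <- if (b_ * c_ == 0) {
    if (a * d_ == 0) NaN else Inf
  } else (a * d_) / (b_ * c_)
  structure(list(gene = gene, category = category, table = tab,
                 p_value = p, odds_ratio = or),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf("Fisher's exact test%s%s: p = %.4g, odds ratio = %s\n",
              if (!is.null(x$gene)) paste0(" gene=", x$gene) else "",
              if (!is.null(x$category)) paste0(" category=", x$category) else "",
              x$p_value, format(x$odds_ratio)))
  print(x$table)
  invisible(x)
}

#' Producer-strain category enrichment against the sequenced library
#'
#' Builds the 2x2 table for one gene slot and category — producer strains
#' with/without a promoter of that category at the slot versus the sequenced
#' library's counts — and applies [fisher_enrichment_test()].
#'
#' @param producer_counts,reference_counts `promoter_counts` tables for
#'   the producer strains and the reference (sequenced library) stage.
#' @param gene Gene slot.
#' @param category Promoter category tested for enrichment.
#' @return An `enrichment_test`.
#' @export
producer_enrichment <- function(producer_counts, reference_counts,
                                gene, category) {
  cell <- function(tab) {
    x <- tab[tab$gene == gene, , drop = FALSE]
    w <- sum(x$count[x$category == category])
    c(w, sum(x$count) - w)
  }
  pr <- cell(producer_counts)
  rf <- cell(reference_counts)
  fisher_enrichment_test(matrix(c(pr[1], rf[1], pr[2], rf[2]), nrow = 2),
                         gene = gene, category = category)
}

#' Bias tests across all gene slots and stages
#'
#' Runs [chi2_bias_test()] for every gene x stage combination present in a
#' count table and reports Benjamini-Hochberg adjusted p-values alongside the
#' raw ones (raw p remains primary; the adjustment is a convenience).
#'
#' @param counts A `promoter_counts` table (possibly several stages rbound).
#' @param design A [library_design()].
#' @param ... Passed to [chi2_bias_test()].
#' @return data.frame: stage, gene, statistic, dof, method, p_value, p_fdr.
#' @export
bias_test_all <- function(counts, design, ...) {
  combos <- unique(counts[, c("stage", "gene")])
  res <- lapply(seq_len(nrow(combos)), function(i)
    chi2_bias_test(counts, design, gene = combos$gene[i],
                   stage = combos$stage[i], ...))
  out <- data.frame(
    stage = combos$stage, gene = combos$gene,
    statistic = vapply(res, `[[`, 0, "statistic"),
    dof = vapply(res, `[[`, 0L, "dof"),
    method = vapply(res, `[[`, "", "method"),
    p_value = vapply(res, `[[`, 0, "p_value"),
    stringsAsFactors = FALSE)
  out$p_fdr <- p.adjust(out$p_value, method = "BH")
  out
}
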