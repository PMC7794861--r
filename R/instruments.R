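# Instrument construction and diagnostics: summary-statistic I/O with
# validation, allele harmonization between exposure and outcome tables,
# weighted genetic risk scores, instrument strength (R^2, F) and
# confounder screening.

ss_required_cols <- c("variant_id", "effect_allele", "other_allele",
                      "eaf", "beta", "se", "pvalue", "n")

valid_alleles <- c("A", "C", "G", "T")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated table with a header row and validates each record.
#' Rows violating the record invariants (non-positive SE, identical or
#' non-ACGT alleles, p outside (0, 1], allele frequency outside (0, 1)) are
#' routed to an exclusion log attached as the `"exclusions"` attribute,
#' never silently dropped. Column-name aliases for other GWAS dialects are
#' supplied via `aliases`, e.g. `list(variant_id = "SNP", beta = "b")`.
#'
#' @param path File path of a TSV with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n` (possibly under
#'   aliased names).
#' @param aliases Named list mapping canonical column names to the names used
#'   in the file.
#' @return A tibble of validated records with attribute `exclusions`
#'   (tibble: `variant_id`, `reason`).
#' @export
read_summary_stats <- function(path, aliases = list()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (canon in names(aliases)) {
    if (aliases[[canon]] %in% names(raw)) {
      names(raw)[names(raw) == aliases[[canon]]] <- canon
    }
  }
  missing <- setdiff(ss_required_cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  validate_summary_stats(raw[ss_required_cols])
}

validate_summary_stats <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  reason <- rep(NA_character_, nrow(tbl))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- flag(!is.na(tbl$se) & tbl$se <= 0, "nonpositive SE")
  reason <- flag(is.na(tbl$se), "missing SE")
  reason <- flag(is.na(tbl$beta), "missing beta")
  reason <- flag(!(toupper(tbl$effect_allele) %in% valid_alleles) |
                   !(toupper(tbl$other_allele) %in% valid_alleles),
                 "invalid allele code")
  reason <- flag(toupper(tbl$effect_allele) == toupper(tbl$other_allele),
                 "identical alleles")
  reason <- flag(!is.na(tbl$pvalue) & (tbl$pvalue <= 0 | tbl$pvalue > 1),
                 "p-value outside (0,1]")
  reason <- flag(!is.na(tbl$eaf) & (tbl$eaf <= 0 | tbl$eaf >= 1),
                 "allele frequency outside (0,1)")
  reason <- flag(duplicated(tbl$variant_id), "duplicate variant id")
  keep <- is.na(reason)
  out <- tbl[keep, , drop = FALSE]
  out$effect_allele <- toupper(out$effect_allele)
  out$other_allele <- toupper(out$other_allele)
  attr(out, "exclusions") <- tibble::tibble(
    variant_id = tbl$variant_id[!keep], reason = reason[!keep]
  )
  out
}

#' Write a summary-statistics table as TSV
#'
#' @param stats A summary-statistics tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  readr::write_tsv(stats[intersect(ss_required_cols, names(stats))], path,
                   progress = FALSE)
  invisible(path)
}

complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(ea, oa) complement(ea) == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects two summary-statistic tables on `variant_id` and aligns the
#' outcome effects to the exposure's effect allele. Direct or strand-
#' complement matches are kept as-is; swapped (or swapped-complement) allele
#' labels flip the outcome beta sign and reflect its allele frequency.
#' Palindromic SNPs (A/T or C/G) cannot be resolved from allele labels: under
#' the default `"strict-exclude"` policy they are excluded; under
#' `"infer-eaf"` they are kept when both allele frequencies are informative
#' (both below 0.42 or both above 0.58) and agree in orientation, excluded
#' otherwise. Monomorphic or missing-SE records are excluded. Every input SNP
#' lands exactly once in either the harmonized set or the exclusion log.
#'
#' @param exposure,outcome Summary-statistics tibbles (see
#'   [read_summary_stats()] / [cohort_to_summary_stats()]).
#' @param palindrome_policy `"strict-exclude"` (default) or `"infer-eaf"`.
#' @return A tibble of class `mr_harmonized` with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`, `eaf_exp`, `eaf_out`; attribute `exclusions` logs removed SNPs.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("strict-exclude", "infer-eaf")) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    abort("both summary-statistic tables must be nonempty.")
  }
  excl <- list()
  drop_snp <- function(id, why) {
    excl[[length(excl) + 1]] <<- tibble::tibble(variant_id = id, reason = why)
  }
  only_exp <- setdiff(exposure$variant_id, outcome$variant_id)
  only_out <- setdiff(outcome$variant_id, exposure$variant_id)
  if (length(only_exp)) drop_snp(only_exp, "absent from outcome table")
  if (length(only_out)) drop_snp(only_out, "absent from exposure table")

  shared <- intersect(exposure$variant_id, outcome$variant_id)
  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]

  keep <- rep(TRUE, length(shared))
  beta_out <- ou$beta
  eaf_out <- ou$eaf
  mono_ex <- if ("monomorphic" %in% names(ex)) ex$monomorphic else rep(FALSE, nrow(ex))
  mono_ou <- if ("monomorphic" %in% names(ou)) ou$monomorphic else rep(FALSE, nrow(ou))
  # plain vectors: this loop runs once per shared SNP
  se_x <- ex$se; se_y <- ou$se
  ea_xs <- ex$effect_allele; oa_xs <- ex$other_allele
  ea_ys <- ou$effect_allele; oa_ys <- ou$other_allele
  eaf_x <- ex$eaf
  bad_any <- is.na(se_x) | se_x <= 0 | mono_ex %in% TRUE |
    is.na(se_y) | se_y <= 0 | mono_ou %in% TRUE
  for (i in seq_along(shared)) {
    bad <- bad_any[i]
    if (bad) {
      drop_snp(shared[i], "missing or nonpositive SE")
      keep[i] <- FALSE
      next
    }
    ea_x <- ea_xs[i]; oa_x <- oa_xs[i]
    ea_y <- ea_ys[i]; oa_y <- oa_ys[i]
    pal <- is_palindromic(ea_x, oa_x)
    if (pal) {
      if (!((ea_y == ea_x && oa_y == oa_x) || (ea_y == oa_x && oa_y == ea_x))) {
        drop_snp(shared[i], "allele mismatch")
        keep[i] <- FALSE
        next
      }
      if (palindrome_policy == "strict-exclude") {
        drop_snp(shared[i], "palindromic SNP (strict-exclude)")
        keep[i] <- FALSE
        next
      }
      fx <- eaf_x[i]; fy <- eaf_out[i]
      informative <- !is.na(fx) && !is.na(fy) &&
        ((fx < 0.42 && fy < 0.42) || (fx > 0.58 && fy > 0.58))
      if (!informative) {
        drop_snp(shared[i], "palindromic SNP with uninformative eaf")
        keep[i] <- FALSE
        next
      }
      # frequencies agree in orientation; align label swaps by sign flip
      if (ea_y == oa_x) {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
      next
    }
    same <- (ea_y == ea_x && oa_y == oa_x) ||
      (ea_y == complement(ea_x) && oa_y == complement(oa_x))
    swapped <- (ea_y == oa_x && oa_y == ea_x) ||
      (ea_y == complement(oa_x) && oa_y == complement(ea_x))
    if (same) {
      next
    } else if (swapped) {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    } else {
      drop_snp(shared[i], "allele mismatch")
      keep[i] <- FALSE
    }
  }
  out <- tibble::tibble(
    variant_id = shared[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    beta_exp = ex$beta[keep], se_exp = ex$se[keep],
    beta_out = beta_out[keep], se_out = ou$se[keep],
    eaf_exp = ex$eaf[keep], eaf_out = eaf_out[keep]
  )
  class(out) <- c("mr_harmonized", class(out))
  attr(out, "exclusions") <- if (length(excl)) {
    dplyr::bind_rows(excl)
  } else {
    tibble::tibble(variant_id = character(0), reason = character(0))
  }
  out
}

#' Exclusion log of a harmonized set or validated table
#'
#' @param x Object carrying an `exclusions` attribute.
#' @return Tibble with columns `variant_id`, `reason`.
#' @export
exclusions <- function(x) {
  attr(x, "exclusions") %||%
    tibble::tibble(variant_id = character(0), reason = character(0))
}

#' Weighted genetic risk score
#'
#' `score_i = sum_j weights_j * g_ij`. Weights are typically the per-allele
#' exposure effects from an exposure GWAS; `weights = NULL` gives the
#' unweighted allele count. Missing genotypes are a hard error: impute
#' explicitly with [impute_genotypes()] first if desired.
#'
#' @param genotypes n x J additive genotype matrix.
#' @param weights Per-SNP weight vector of length J, or `NULL` for unweighted.
#' @return Numeric score vector of length n.
#' @export
build_grs <- function(genotypes, weights = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(weights)) weights <- rep(1, ncol(genotypes))
  if (length(weights) != ncol(genotypes)) {
    abort("`weights` length must equal the number of genotype columns.")
  }
  if (anyNA(genotypes)) {
    abort("missing genotypes are not allowed; impute or exclude upstream.")
  }
  drop(genotypes %*% weights)
}

#' Mean-impute missing genotypes by expected allele count
#'
#' Replaces missing entries of column j by `2 * eaf_j`. Offered as an
#' explicit preprocessing step; [build_grs()] never imputes silently.
#'
#' @param genotypes Genotype matrix possibly containing `NA`.
#' @param eaf Effect-allele frequencies per column; default estimated from
#'   the observed entries.
#' @return Matrix without missing values.
#' @export
impute_genotypes <- function(genotypes, eaf = NULL) {
  genotypes <- as.matrix(genotypes)
  eaf <- eaf %||% (colMeans(genotypes, na.rm = TRUE) / 2)
  for (j in seq_len(ncol(genotypes))) {
    miss <- is.na(genotypes[, j])
    if (any(miss)) genotypes[miss, j] <- 2 * eaf[j]
  }
  genotypes
}

#' Instrument strength: first-stage R-squared and F-statistic
#'
#' Regresses the exposure on the instrument score and reports
#' `F = ((n - k - 1) / k) * R^2 / (1 - R^2)` with `k` the number of
#' instruments collapsed into the score (k = 1 for a single GRS). A perfect
#' fit reports `f_statistic = Inf`.
#'
#' @param score Instrument (GRS) vector.
#' @param exposure Exposure vector of the same length.
#' @param k Number of instruments represented by the score.
#' @return One-row tibble: `f_statistic`, `r_squared`, `n`, `k`.
#' @export
instrument_strength <- function(score, exposure, k = 1) {
  n <- length(score)
  stopifnot(length(exposure) == n)
  if (n < k + 2) abort("need at least k + 2 observations.")
  if (var(score) <= .Machine$double.eps) abort("degenerate instrument: zero-variance score.")
  r2 <- cor(score, exposure)^2
  f <- if (1 - r2 < .Machine$double.eps) Inf else ((n - k - 1) / k) * r2 / (1 - r2)
  tibble::tibble(f_statistic = f, r_squared = r2, n = n, k = k)
}

#' Screen covariates for association with the instrument
#'
#' Regresses each covariate on the standardized score (effects reported per
#' SD of the score). No multiplicity adjustment: every association with
#' p < 0.05 is flagged for the analyst, matching confounder-screening
#' practice for genetic instruments. Constant covariates are skipped with a
#' log entry.
#'
#' @param score Instrument score vector.
#' @param covariates Data frame of candidate confounders.
#' @return Tibble: `covariate`, `beta` (per SD of score), `se`, `pvalue`,
#'   `flagged`; skipped covariates recorded in the `"skipped"` attribute.
#' @export
confounder_screen <- function(score, covariates) {
  covariates <- tibble::as_tibble(covariates)
  if (nrow(covariates) < 3) abort("need at least 3 rows.")
  stopifnot(nrow(covariates) == length(score))
  z <- as.numeric(scale(score))
  skipped <- character(0)
  rows <- purrr::map(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (!is.numeric(v) || var(v, na.rm = TRUE) <= .Machine$double.eps) {
      skipped <<- c(skipped, nm)
      return(NULL)
    }
    fit <- lm(v ~ z)
    cf <- suppressWarnings(summary(fit))$coefficients
    tibble::tibble(covariate = nm, beta = cf[2, 1], se = cf[2, 2],
                   pvalue = cf[2, 4], flagged = cf[2, 4] < 0.05)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}
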