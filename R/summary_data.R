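# Reading, validation, instrument selection and harmonization of GWAS
# summary statistics.

GWAS_FIELDS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pval", "n")
GWAS_REQUIRED <- setdiff(GWAS_FIELDS, c("eaf", "n"))

PALINDROMIC_PAIRS <- c("A/T", "T/A", "C/G", "G/C")

is_palindromic <- function(ea, oa) paste(ea, oa, sep = "/") %in% PALINDROMIC_PAIRS

#' Construct a validated GWAS summary-statistics table
#'
#' Wraps one trait's per-SNP association estimates (effect sizes on the
#' log-odds scale for binary traits, SD units for quantitative traits) in a
#' validated container. Rows violating the per-variant invariants
#' (`se > 0`, `pval` in (0,1], single-letter A/C/G/T alleles,
#' `effect_allele != other_allele`, `pos >= 1`, duplicated `variant_id`)
#' are dropped with a message stating the count.
#'
#' @param data data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval` and optionally
#'   `eaf`, `n`.
#' @param trait_name Trait label.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param quiet Suppress the dropped-row message.
#' @return An object of class `gwas_table` with elements `trait_name`,
#'   `trait_type`, `data` (validated rows, input order preserved) and
#'   `dropped` (a data.frame of rejected rows with a `reason` code).
#' @export
gwas_table <- function(data, trait_name, trait_type = c("binary", "quantitative"),
                       quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  data <- as.data.frame(data)
  missing_cols <- setdiff(GWAS_REQUIRED, names(data))
  assert_that(length(missing_cols) == 0L, "mrscreen_schema_error",
              "required column(s) absent: %s", paste(missing_cols, collapse = ", "))
  if (!"eaf" %in% names(data)) data$eaf <- NA_real_
  if (!"n" %in% names(data)) data$n <- NA_integer_
  data <- data[GWAS_FIELDS]

  data$variant_id <- as.character(data$variant_id)
  data$chrom <- as.character(data$chrom)
  data$pos <- as.integer(data$pos)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) data[[col]] <- as.numeric(data[[col]])
  data$n <- as.numeric(data$n)
  # eaf outside (0,1) is treated as missing rather than invalid
  data$eaf[!is.na(data$eaf) & (data$eaf <= 0 | data$eaf >= 1)] <- NA_real_

  reason <- rep(NA_character_, nrow(data))
  bad <- function(cond, why) reason[is.na(reason) & cond] <<- why
  nucl <- c("A", "C", "G", "T")
  bad(is.na(data$variant_id) | data$variant_id == "", "missing_id")
  bad(is.na(data$beta) | !is.finite(data$beta), "missing_beta")
  bad(is.na(data$se) | data$se <= 0, "invalid_se")
  bad(is.na(data$pval) | data$pval <= 0 | data$pval > 1, "invalid_pval")
  bad(!(data$effect_allele %in% nucl) | !(data$other_allele %in% nucl), "invalid_allele")
  bad(data$effect_allele == data$other_allele, "identical_alleles")
  bad(is.na(data$pos) | data$pos < 1, "invalid_pos")
  bad(duplicated(data$variant_id), "duplicate_id")

  keep <- is.na(reason)
  dropped <- data.frame(variant_id = data$variant_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  data <- data[keep, , drop = FALSE]
  rownames(data) <- NULL
  assert_that(nrow(data) > 0L, "mrscreen_empty_input",
              "no valid rows for trait '%s'", trait_name)
  if (!quiet && nrow(dropped) > 0L)
    message(sprintf("[%s] dropped %d invalid row(s)", trait_name, nrow(dropped)))

  structure(list(trait_name = trait_name, trait_type = trait_type,
                 data = data, dropped = dropped),
            class = "gwas_table")
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("<gwas_table> %s (%s): %d variants\n",
              x$trait_name, x$trait_type, nrow(x$data)))
  print(head(x$data, 4L))
  invisible(x)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab- or comma-delimited file (gzip accepted) with a header row,
#' renames columns via `column_map`, and validates rows as in [gwas_table()].
#'
#' @param path File path.
#' @param column_map Named character vector mapping standard field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to source column names. Fields absent from the
#'   map are looked up under their standard names.
#' @param trait_type `"binary"` or `"quantitative"`.
#' @param trait_name Trait label; defaults to the file name without extension.
#' @param quiet Suppress the dropped-row message.
#' @return A [gwas_table()].
#' @export
read_gwas_table <- function(path, column_map = NULL,
                            trait_type = c("binary", "quantitative"),
                            trait_name = NULL, quiet = FALSE) {
  trait_type <- match.arg(trait_type)
  assert_that(file.exists(path), "mrscreen_io_error", "file not found: %s", path)
  trait_name <- trait_name %||% sub("\\.(tsv|txt|csv)(\\.gz)?$", "", basename(path))
  raw <- as.data.frame(data.table::fread(path, header = TRUE, data.table = FALSE))
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      src <- column_map[[std]]
      assert_that(src %in% names(raw), "mrscreen_schema_error",
                  "mapped column '%s' (for field '%s') absent in %s", src, std, path)
      names(raw)[names(raw) == src] <- std
    }
  }
  gwas_table(raw, trait_name = trait_name, trait_type = trait_type, quiet = quiet)
}

#' Write a GWAS summary-statistics table as TSV
#'
#' Emits the standard column order read back by [read_gwas_table()].
#' @param x A [gwas_table()].
#' @param path Output path.
#' @export
write_gwas_table <- function(x, path) {
  stopifnot(inherits(x, "gwas_table"))
  write_tsv(x$data[GWAS_FIELDS], path)
}

#' Per-SNP instrument strength (F-statistic and variance explained)
#'
#' The single-variant Wald F-statistic `F = (beta/se)^2` and the variance in
#' the exposure explained by the SNP, `R2 = F / (F + n - 2)`. When the effect
#' allele frequency is available, the allele-frequency form
#' `R2_af = 2*eaf*(1-eaf)*beta^2` (standardized phenotype) is also reported.
#' Instruments with `F < 10` are conventionally considered weak.
#'
#' @param beta,se Per-allele effect and its standard error.
#' @param n Sample size of the exposure GWAS (> 2).
#' @param eaf Optional effect-allele frequency.
#' @return List with `F`, `R2`, `R2_af` (NA when `eaf` missing) and
#'   logical `weak`.
#' @export
instrument_strength <- function(beta, se, n, eaf = NA_real_) {
  assert_that(all(se > 0), "mrscreen_domain_error", "se must be positive")
  assert_that(all(is.na(n) | n > 2), "mrscreen_domain_error", "n must exceed 2")
  Fstat <- (beta / se)^2
  R2 <- ifelse(is.na(n), NA_real_, Fstat / (Fstat + n - 2))
  R2_af <- ifelse(is.na(eaf), NA_real_, 2 * eaf * (1 - eaf) * beta^2)
  list(F = Fstat, R2 = R2, R2_af = R2_af, weak = Fstat < 10)
}

# Greedy distance/LD clumping. Candidates sorted by (pval, chrom, pos,
# variant_id); a candidate is rejected when an already-accepted variant lies
# within `clump_kb` kilobases on the same chromosome and either no LD matrix
# was supplied, the pair is absent from it, or its r^2 exceeds `clump_r2`.
clump_variants <- function(df, clump_kb, clump_r2, ld = NULL) {
  ord <- order(df$pval, df$chrom, df$pos, df$variant_id)
  df <- df[ord, , drop = FALSE]
  window <- clump_kb * 1000
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    acc <- which(keep)
    near <- acc[df$chrom[acc] == df$chrom[i] &
                abs(df$pos[acc] - df$pos[i]) <= window]
    rejected <- FALSE
    for (a in near) {
      if (is.null(ld)) { rejected <- TRUE; break }
      ida <- df$variant_id[a]; idi <- df$variant_id[i]
      if (!(ida %in% rownames(ld)) || !(idi %in% colnames(ld))) {
        rejected <- TRUE; break  # unresolved pair: conservative
      }
      if (ld[ida, idi] > clump_r2) { rejected <- TRUE; break }
    }
    keep[i] <- !rejected
  }
  df[keep, , drop = FALSE]
}

#' Select genetic instruments for an exposure
#'
#' Filters to genome-wide-significant variants (`pval <= primary_p`), clumps
#' them greedily by ascending p-value within a `clump_kb` window (LD r^2
#' filtering only when an LD matrix is supplied; otherwise distance alone
#' decides, which is strictly more conservative), and falls back to the
#' lenient threshold when fewer than `min_snps` instruments survive.
#'
#' @param stats A [gwas_table()] for the exposure.
#' @param primary_p,lenient_p Genome-wide and fallback significance
#'   thresholds (defaults 5e-8 and 5e-6).
#' @param min_snps Minimum instrument count below which the lenient
#'   threshold is used (default 3, the minimum for Egger/weighted-median).
#' @param clump_kb,clump_r2 Clumping window (kilobases, inclusive) and LD
#'   r^2 threshold (defaults 10000 kb and 0.001).
#' @param ld Optional square LD r^2 matrix with variant ids as dimnames.
#' @return An object of class `instrument_set`: `exposure`, `trait_type`,
#'   `threshold_used`, and `variants` (validated rows plus per-SNP `F`,
#'   `R2`, `R2_af`, `weak`).
#' @export
select_instruments <- function(stats, primary_p = 5e-8, lenient_p = 5e-6,
                               min_snps = 3L, clump_kb = 10000L,
                               clump_r2 = 0.001, ld = NULL) {
  stopifnot(inherits(stats, "gwas_table"))
  df <- stats$data
  pick <- function(p) clump_variants(df[df$pval <= p, , drop = FALSE],
                                     clump_kb, clump_r2, ld)
  sel <- pick(primary_p)
  threshold_used <- primary_p
  if (nrow(sel) < min_snps) {
    sel <- pick(lenient_p)
    threshold_used <- lenient_p
  }
  assert_that(nrow(sel) > 0L, "mrscreen_empty_instruments",
              "no instrument passes p <= %g for trait '%s'",
              lenient_p, stats$trait_name)
  strength <- instrument_strength(sel$beta, sel$se, sel$n, sel$eaf)
  sel$F <- strength$F
  sel$R2 <- strength$R2
  sel$R2_af <- strength$R2_af
  sel$weak <- strength$weak
  rownames(sel) <- NULL
  structure(list(exposure = stats$trait_name, trait_type = stats$trait_type,
                 threshold_used = threshold_used, variants = sel),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d instruments (p <= %g), median F = %.1f\n",
              x$exposure, nrow(x$variants), x$threshold_used,
              median(x$variants$F)))
  invisible(x)
}

# allele orientation of a candidate row against reference (ea, oa):
# "same", "swap" or "mismatch"
allele_orientation <- function(ea_ref, oa_ref, ea, oa) {
  ifelse(ea == ea_ref & oa == oa_ref, "same",
         ifelse(ea == oa_ref & oa == ea_ref, "swap", "mismatch"))
}

#' Construct a harmonized exposure-outcome dataset directly
#'
#' Low-level constructor for an instrument-by-factor dataset already aligned
#' to a shared effect allele, as produced by [harmonize()]. Useful for
#' simulation studies and for feeding externally harmonized estimates into
#' the estimators.
#'
#' @param bx J x K matrix (or length-J vector) of exposure effects.
#' @param sx Matching matrix/vector of exposure standard errors.
#' @param by,sy Length-J outcome effects and standard errors.
#' @param exposure_names,outcome_name Trait labels.
#' @param variant_ids Instrument identifiers (default `snp1..snpJ`).
#' @param variants Optional data.frame of variant annotation
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`).
#' @param drops Optional drop-log data.frame (`variant_id`, `reason`).
#' @return Object of class `harmonized_data`.
#' @export
harmonized_dataset <- function(bx, sx, by, sy,
                               exposure_names = NULL, outcome_name = "outcome",
                               variant_ids = NULL, variants = NULL,
                               drops = NULL) {
  bx <- as.matrix(bx); sx <- as.matrix(sx)
  J <- nrow(bx); K <- ncol(bx)
  assert_that(J >= 1L, "mrscreen_empty_harmonization", "no instruments")
  stopifnot(length(by) == J, length(sy) == J, all(dim(sx) == dim(bx)))
  assert_that(all(sx > 0) && all(sy > 0), "mrscreen_domain_error",
              "all standard errors must be strictly positive")
  exposure_names <- exposure_names %||% colnames(bx) %||% paste0("exposure", seq_len(K))
  variant_ids <- variant_ids %||% paste0("snp", seq_len(J))
  dimnames(bx) <- dimnames(sx) <- list(variant_ids, exposure_names)
  drops <- drops %||% data.frame(variant_id = character(), reason = character(),
                                 stringsAsFactors = FALSE)
  structure(list(
    exposure_names = exposure_names, outcome_name = outcome_name,
    variant_ids = variant_ids, bx = bx, sx = sx,
    by = setNames(as.numeric(by), variant_ids),
    sy = setNames(as.numeric(sy), variant_ids),
    variants = variants, drops = drops,
    dropped_palindromic = drops$variant_id[drops$reason == "palindromic"],
    dropped_missing = drops$variant_id[drops$reason %in%
                                       c("missing_outcome", "missing_exposure")]
  ), class = "harmonized_data")
}

#' @export
print.harmonized_data <- function(x, ...) {
  cat(sprintf("<harmonized_data> %s -> %s: %d instruments, %d dropped\n",
              paste(x$exposure_names, collapse = " + "), x$outcome_name,
              length(x$variant_ids), nrow(x$drops)))
  invisible(x)
}

#' Number of instruments in a harmonized dataset
#' @param h A `harmonized_data` object.
#' @export
n_instruments <- function(h) length(h$variant_ids)

#' Subset a harmonized dataset by variant id
#' @param h A `harmonized_data` object.
#' @param keep Variant ids to retain (order follows `h`).
#' @export
subset_harmonized <- function(h, keep) {
  idx <- which(h$variant_ids %in% keep)
  assert_that(length(idx) >= 1L, "mrscreen_empty_harmonization",
              "subset removes every instrument")
  harmonized_dataset(h$bx[idx, , drop = FALSE], h$sx[idx, , drop = FALSE],
                     h$by[idx], h$sy[idx],
                     exposure_names = h$exposure_names,
                     outcome_name = h$outcome_name,
                     variant_ids = h$variant_ids[idx],
                     variants = if (!is.null(h$variants))
                       h$variants[idx, , drop = FALSE] else NULL,
                     drops = h$drops)
}

#' Harmonize exposure instruments with an outcome GWAS
#'
#' Aligns each instrument's outcome (and, multivariable, other exposures')
#' association to the exposure's effect allele. Swapped alleles negate the
#' beta and flip the effect-allele frequency; allele pairs that are neither
#' identical nor swapped are dropped as mismatched; palindromic variants
#' (A/T or C/G) are dropped unconditionally because strand cannot be
#' resolved from alleles alone. Every drop is recorded with a reason code.
#'
#' @param exposure_sets One `instrument_set` or a list of them (K factors).
#' @param outcome A [gwas_table()] for the outcome.
#' @param multivariable Build the union-of-instruments J x K design; requires
#'   every factor's beta at every retained variant (see `exposure_tables`).
#' @param exposure_tables Optional list of full [gwas_table()]s, one per
#'   exposure, used to look up a factor's association at instruments selected
#'   for *other* factors; variants missing from any factor are dropped.
#' @return A `harmonized_data` object (see [harmonized_dataset()]).
#' @export
harmonize <- function(exposure_sets, outcome, multivariable = FALSE,
                      exposure_tables = NULL) {
  if (inherits(exposure_sets, "instrument_set")) exposure_sets <- list(exposure_sets)
  stopifnot(inherits(outcome, "gwas_table"))
  K <- length(exposure_sets)
  if (K > 1L) multivariable <- TRUE
  exposure_names <- vapply(exposure_sets, `[[`, "", "exposure")

  # union of instruments, ordered by (chrom, pos, id); reference alleles come
  # from the first exposure set carrying the variant
  all_v <- do.call(rbind, lapply(exposure_sets, function(s)
    s$variants[c("variant_id", "chrom", "pos", "effect_allele", "other_allele", "eaf")]))
  all_v <- all_v[!duplicated(all_v$variant_id), , drop = FALSE]
  all_v <- all_v[order(all_v$chrom, all_v$pos, all_v$variant_id), , drop = FALSE]

  out <- outcome$data
  out_idx <- match(all_v$variant_id, out$variant_id)

  drops <- list()
  note_drop <- function(ids, reason) {
    if (length(ids)) drops[[length(drops) + 1L]] <<-
      data.frame(variant_id = ids, reason = reason, stringsAsFactors = FALSE)
  }

  pal <- is_palindromic(all_v$effect_allele, all_v$other_allele)
  note_drop(all_v$variant_id[pal], "palindromic")
  miss_out <- !pal & is.na(out_idx)
  note_drop(all_v$variant_id[miss_out], "missing_outcome")
  keep <- !pal & !miss_out

  orient <- rep(NA_character_, nrow(all_v))
  orient[keep] <- allele_orientation(
    all_v$effect_allele[keep], all_v$other_allele[keep],
    out$effect_allele[out_idx[keep]], out$other_allele[out_idx[keep]])
  mism <- keep & orient == "mismatch"
  note_drop(all_v$variant_id[mism], "allele_mismatch")
  keep <- keep & orient != "mismatch"

  by <- ifelse(orient == "swap", -out$beta[out_idx], out$beta[out_idx])
  sy <- out$se[out_idx]

  # per-factor exposure betas aligned to the reference allele
  bx <- matrix(NA_real_, nrow(all_v), K)
  sx <- matrix(NA_real_, nrow(all_v), K)
  for (k in seq_len(K)) {
    src <- exposure_sets[[k]]$variants
    if (!is.null(exposure_tables)) {
      extra <- exposure_tables[[k]]$data
      extra <- extra[!(extra$variant_id %in% src$variant_id), , drop = FALSE]
      src <- rbind(src[GWAS_FIELDS], extra[GWAS_FIELDS])
    }
    idx <- match(all_v$variant_id, src$variant_id)
    ok <- !is.na(idx)
    ori <- rep(NA_character_, nrow(all_v))
    ori[ok] <- allele_orientation(all_v$effect_allele[ok], all_v$other_allele[ok],
                                  src$effect_allele[idx[ok]], src$other_allele[idx[ok]])
    bad <- ok & ori == "mismatch"
    if (any(bad & keep)) note_drop(all_v$variant_id[bad & keep], "allele_mismatch")
    keep <- keep & !bad
    bx[ok, k] <- ifelse(ori[ok] == "swap", -src$beta[idx[ok]], src$beta[idx[ok]])
    sx[ok, k] <- src$se[idx[ok]]
  }
  miss_exp <- keep & rowSums(is.na(bx) | is.na(sx)) > 0
  if (multivariable) {
    note_drop(all_v$variant_id[miss_exp], "missing_exposure")
    keep <- keep & !miss_exp
  }

  drops <- if (length(drops)) do.call(rbind, drops) else
    data.frame(variant_id = character(), reason = character(), stringsAsFactors = FALSE)
  drops <- drops[!duplicated(drops$variant_id), , drop = FALSE]
  drops <- drops[!(drops$variant_id %in% all_v$variant_id[keep]), , drop = FALSE]
  rownames(drops) <- NULL
  assert_that(any(keep), "mrscreen_empty_harmonization",
              "no instrument survives harmonization of %s against %s",
              paste(exposure_names, collapse = "+"), outcome$trait_name)

  harmonized_dataset(bx[keep, , drop = FALSE], sx[keep, , drop = FALSE],
                     by[keep], sy[keep],
                     exposure_names = exposure_names,
                     outcome_name = outcome$trait_name,
                     variant_ids = all_v$variant_id[keep],
                     variants = {
                       v <- all_v[keep, , drop = FALSE]; rownames(v) <- NULL; v
                     },
                     drops = drops)
}

#' Export a harmonized dataset as TSV
#'
#' Fixed column order: variant_id, chrom, pos, ea, oa, eaf, then per-factor
#' bx/sx columns, by, sy, F, R2. A companion drop log is written alongside
#' when any variant was dropped.
#' @param h A `harmonized_data` object.
#' @param path Output TSV path; drop log goes to `<path>.drops.tsv`.
#' @export
write_harmonized <- function(h, path) {
  K <- length(h$exposure_names)
  ann <- h$variants %||% data.frame(
    variant_id = h$variant_ids, chrom = NA, pos = NA,
    effect_allele = NA, other_allele = NA, eaf = NA)
  df <- data.frame(variant_id = h$variant_ids,
                   chrom = ann$chrom, pos = ann$pos,
                   ea = ann$effect_allele, oa = ann$other_allele, eaf = ann$eaf,
                   stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    df[[paste0("bx_", h$exposure_names[k])]] <- h$bx[, k]
    df[[paste0("sx_", h$exposure_names[k])]] <- h$sx[, k]
  }
  df$by <- h$by
  df$sy <- h$sy
  df$F <- (h$bx[, 1] / h$sx[, 1])^2
  df$R2 <- NA_real_
  write_tsv(df, path)
  if (nrow(h$drops)) write_tsv(h$drops, paste0(path, ".drops.tsv"))
  invisible(path)
}
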