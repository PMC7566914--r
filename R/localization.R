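#' Summarize replicate Ct calls for one (strain, gene)
#'
#' Mean and sample standard deviation (n-1 denominator) over the calls that
#' crossed the threshold. If no call crossed, the summary is a
#' no-amplification sentinel (`mean_ct = NA`, `n = 0`) that flows through
#' classification as UNKNOWN rather than erroring.
#'
#' @param ct numeric vector of Ct values (`NA` = no amplification) or a
#'   list of `ct_call` objects.
#' @param strain_id,gene_id labels carried on the summary.
#' @return A list of class `gene_summary` with `strain_id`, `gene_id`,
#'   `mean_ct`, `sd_ct`, `n`, `no_amplification`.
#' @export
summarize_ct <- function(ct, strain_id = NA_character_, gene_id = NA_character_) {
  if (is.list(ct)) ct <- vapply(ct, function(x) x$ct, numeric(1))
  ct <- ct[!is.na(ct)]
  if (!length(ct))
    return(gene_summary(strain_id, gene_id, NA_real_, NA_real_, 0L))
  gene_summary(strain_id, gene_id, mean(ct),
               if (length(ct) > 1L) stats::sd(ct) else 0, length(ct))
}

#' Construct a gene summary (one row of a Ct summary table)
#'
#' @param strain_id,gene_id labels.
#' @param mean_ct,sd_ct mean and standard deviation of replicate Ct values
#'   (`mean_ct = NA` encodes no amplification).
#' @param n number of replicate reactions that amplified.
#' @export
gene_summary <- function(strain_id, gene_id, mean_ct, sd_ct, n) {
  structure(list(strain_id = as.character(strain_id),
                 gene_id = as.character(gene_id),
                 mean_ct = as.numeric(mean_ct), sd_ct = as.numeric(sd_ct),
                 n = as.integer(n),
                 no_amplification = is.na(mean_ct) || n == 0L),
            class = "gene_summary")
}

#' Compare Ct values of two genes
#'
#' With per-replicate vectors, runs a paired two-sample t-test on
#' replicate-matched differences (pairing by position, i.e. by
#' (biological, technical) replicate index). With [gene_summary] inputs, the
#' pairing covariance is unavailable, so a Welch two-sample t statistic is
#' computed from the summaries (Welch-Satterthwaite degrees of freedom) and
#' labelled as such. Zero-variance comparisons are reported with a
#' `degenerate` flag instead of NaN: p = 1 when the means are equal
#' (maximally non-significant), p = 0 otherwise.
#'
#' @param goi,ref gene-of-interest and reference: equal-length numeric
#'   vectors of replicate Cts, or two [gene_summary] objects.
#' @return A list of class `ttest_result` with `statistic`, `df`,
#'   `p_value`, `method` (`"paired"` or `"welch_from_summary"`) and
#'   `degenerate`.
#' @export
compare_genes <- function(goi, ref) {
  if (inherits(goi, "gene_summary") && inherits(ref, "gene_summary"))
    return(welch_from_summary(goi$mean_ct, goi$sd_ct, goi$n,
                              ref$mean_ct, ref$sd_ct, ref$n))
  goi <- as.numeric(goi); ref <- as.numeric(ref)
  if (length(goi) != length(ref))
    stop_petfloc("parameter", "paired comparison needs equal replicate counts")
  keep <- !is.na(goi) & !is.na(ref)
  goi <- goi[keep]; ref <- ref[keep]
  if (length(goi) < 2L)
    stop_petfloc("insufficient_replicates", "need >= 2 paired replicates")
  d <- goi - ref
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(ttest_result(0, length(d) - 1, 1, "paired", degenerate = TRUE))
    return(ttest_result(sign(mean(d)) * Inf, length(d) - 1, 0, "paired",
                        degenerate = TRUE))
  }
  tt <- stats::t.test(goi, ref, paired = TRUE)
  ttest_result(unname(tt$statistic), unname(tt$parameter), tt$p.value, "paired")
}

#' Welch two-sample t-test from summary statistics
#'
#' @param m1,s1,n1 mean, sd, n of the first group.
#' @param m2,s2,n2 mean, sd, n of the second group.
#' @return A `ttest_result` (see [compare_genes]).
#' @export
welch_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (is.na(m1) || is.na(m2))
    stop_petfloc("insufficient_replicates", "summary with no amplification")
  if (n1 < 2L || n2 < 2L)
    stop_petfloc("insufficient_replicates", "need n >= 2 in both groups")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  if (v1 + v2 == 0) {
    if (m1 == m2)
      return(ttest_result(0, n1 + n2 - 2, 1, "welch_from_summary", degenerate = TRUE))
    return(ttest_result(sign(m1 - m2) * Inf, n1 + n2 - 2, 0,
                        "welch_from_summary", degenerate = TRUE))
  }
  tstat <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  ttest_result(tstat, df, p, "welch_from_summary")
}

ttest_result <- function(statistic, df, p_value, method, degenerate = FALSE) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, degenerate = degenerate),
            class = "ttest_result")
}

#' Call the genomic compartment of the gene of interest for one strain
#'
#' Applies the dual-reference decision rule. The gene of interest is
#' compared against a single-copy nuclear reference (its fold should be
#' near 1 if nuclear) and a single-copy plastid-encoded reference (its fold
#' tracks plastid genome copies per cell if plastid-retained). With
#' p-values from the two comparisons at level `alpha`:
#' non-significant vs nuclear and significant vs plastid calls
#' NUCLEAR_TRANSFER; the mirror image calls PLASTID_RETENTION; both
#' significant triggers a log2 magnitude tie-break (which reference's copy
#' number is the gene of interest closer to); both non-significant is
#' AMBIGUOUS. A gene of interest that never amplified is UNKNOWN.
#'
#' @param s_goi,s_nuc,s_cp [gene_summary] for the gene of interest, the
#'   nuclear reference and the plastid reference.
#' @param alpha significance level (default 0.01).
#' @param p_vs_nuc,p_vs_cp optional externally computed p-values (e.g. from
#'   a published table); when `NULL` they are computed with
#'   [welch_from_summary].
#' @return A list of class `localization_call` with `strain_id`, `status`
#'   (one of `"NUCLEAR_TRANSFER"`, `"PLASTID_RETENTION"`, `"AMBIGUOUS"`,
#'   `"UNKNOWN"`), `fold_goi`, `fold_cp` (relative copy numbers vs the
#'   nuclear reference), `p_vs_nuc`, `p_vs_cp`, `tie_break_used`.
#' @export
classify_strain <- function(s_goi, s_nuc, s_cp, alpha = 0.01,
                            p_vs_nuc = NULL, p_vs_cp = NULL) {
  stopifnot(inherits(s_goi, "gene_summary"), inherits(s_nuc, "gene_summary"),
            inherits(s_cp, "gene_summary"))
  strain <- s_goi$strain_id
  if (s_goi$no_amplification)
    return(localization_call(strain, "UNKNOWN",
                             relative_copy_number(NA, NA),
                             relative_copy_number(NA, NA),
                             NA_real_, NA_real_, FALSE))
  if (s_nuc$no_amplification || s_cp$no_amplification)
    stop_petfloc("reference_missing",
                 sprintf("strain %s: reference gene did not amplify", strain))
  cn_goi <- relative_copy_number(s_nuc$mean_ct, s_goi$mean_ct)
  cn_cp <- relative_copy_number(s_nuc$mean_ct, s_cp$mean_ct)
  if (cn_cp$fold <= 1)
    stop_petfloc("reference_qc_failure",
                 sprintf("strain %s: plastid reference fold %.3g <= 1; plastid genomes should be enriched over nuclear",
                         strain, cn_cp$fold))
  if (is.null(p_vs_nuc))
    p_vs_nuc <- compare_genes(s_goi, s_nuc)$p_value
  if (is.null(p_vs_cp))
    p_vs_cp <- compare_genes(s_goi, s_cp)$p_value
  sig_nuc <- p_vs_nuc < alpha
  sig_cp <- p_vs_cp < alpha
  tie <- FALSE
  status <- if (!sig_nuc && sig_cp) {
    "NUCLEAR_TRANSFER"
  } else if (sig_nuc && !sig_cp) {
    "PLASTID_RETENTION"
  } else if (sig_nuc && sig_cp) {
    tie <- TRUE
    d_nuc <- abs(log2(cn_goi$fold))
    d_cp <- abs(log2(cn_goi$fold) - log2(cn_cp$fold))
    if (d_nuc < d_cp) "NUCLEAR_TRANSFER"
    else if (d_cp < d_nuc) "PLASTID_RETENTION"
    else "AMBIGUOUS"
  } else {
    warn_petfloc("reference_qc",
                 sprintf("strain %s: gene of interest differs from neither reference at alpha = %g",
                         strain, alpha))
    "AMBIGUOUS"
  }
  localization_call(strain, status, cn_goi, cn_cp, p_vs_nuc, p_vs_cp, tie)
}

localization_call <- function(strain_id, status, cn_goi, cn_cp,
                              p_vs_nuc, p_vs_cp, tie_break_used) {
  structure(list(strain_id = strain_id, status = status,
                 fold_goi = cn_goi, fold_cp = cn_cp,
                 p_vs_nuc = p_vs_nuc, p_vs_cp = p_vs_cp,
                 tie_break_used = tie_break_used),
            class = "localization_call")
}

#' Read a Ct summary CSV (printed-table format)
#'
#' Columns `strain,gene,mean_ct,sd_ct,n,p_value`; empty `mean_ct` encodes
#' no amplification; `p_value` may be empty or `"-"` (as printed for the
#' gene-of-interest row).
#'
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_summary_csv <- function(path) {
  if (!file.exists(path))
    stop_petfloc("file_not_found", sprintf("summary file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA", "-"))
  needed <- c("strain", "gene", "mean_ct", "sd_ct", "n", "p_value")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop_petfloc("format", sprintf("summary CSV is missing column(s): %s",
                                   paste(missing, collapse = ", ")))
  df$mean_ct <- as.numeric(df$mean_ct)
  df$sd_ct <- as.numeric(df$sd_ct)
  df$n <- as.integer(df$n)
  df$p_value <- as.numeric(df$p_value)
  df
}

#' Run the localization pipeline over a whole table or plate
#'
#' Accepts (i) a summary data.frame as from [read_summary_csv] -- p-values
#' are taken from the `p_value` column of the reference-gene rows when
#' present, otherwise computed by Welch's test from the summaries; (ii) a
#' replicate-level Ct data.frame with columns
#' `strain,gene,bio_rep,tech_rep,ct` -- p-values come from replicate-paired
#' t-tests; or (iii) a list of [amp_curve] objects, which are Ct-called
#' first.
#'
#' @param x input table or curve list.
#' @param alpha significance level.
#' @param goi,nuclear_ref,plastid_ref gene labels (defaults `"petF"`,
#'   `"tef1a"`, `"rbcS"`).
#' @param threshold,baseline_cycles curve-level Ct-calling parameters (used
#'   only for curve input).
#' @return A data.frame with one row per strain, ordered by strain label:
#'   `strain`, `status`, `fold_goi`, `fold_goi_rounded`, `fold_cp`,
#'   `fold_cp_rounded`, `p_vs_nuc`, `p_vs_cp`, `tie_break_used`, `note`.
#'   Strains whose references fail are kept with status `NA` and the error
#'   message in `note`.
#' @export
run_localization <- function(x, alpha = 0.01, goi = "petF",
                             nuclear_ref = "tef1a", plastid_ref = "rbcS",
                             threshold = 0.2, baseline_cycles = 5L) {
  if (is.list(x) && !is.data.frame(x) && all(vapply(x, inherits, TRUE, "amp_curve"))) {
    x <- curves_to_ct_table(x, threshold = threshold,
                            baseline_cycles = baseline_cycles)
  }
  stopifnot(is.data.frame(x))
  if (!nrow(x))
    return(empty_calls_df())
  if ("ct" %in% names(x)) run_localization_ct(x, alpha, goi, nuclear_ref, plastid_ref)
  else run_localization_summary(x, alpha, goi, nuclear_ref, plastid_ref)
}

#' Ct-call every well of a plate
#'
#' @param curves list of [amp_curve] objects.
#' @param threshold,baseline_cycles see [call_ct] and [baseline_correct].
#' @param efficiency also estimate per-well amplification efficiency.
#' @return A data.frame `well,strain,gene,bio_rep,tech_rep,ct` (plus
#'   `efficiency_mult`, `r2` when `efficiency = TRUE`; wells with no
#'   exponential phase get `NA`).
#' @export
curves_to_ct_table <- function(curves, threshold = 0.2, baseline_cycles = 5L,
                               efficiency = FALSE) {
  rows <- lapply(curves, function(cv) {
    bc <- baseline_correct(cv, baseline_cycles)
    cc <- call_ct(bc, threshold)
    out <- data.frame(well = cv$well_id, strain = cv$strain_id,
                      gene = cv$gene_id, bio_rep = cv$bio_replicate,
                      tech_rep = cv$tech_replicate, ct = cc$ct,
                      stringsAsFactors = FALSE)
    if (efficiency) {
      est <- tryCatch(estimate_efficiency(bc),
                      petfloc_no_exponential_phase = function(e) NULL)
      out$efficiency_mult <- if (is.null(est)) NA_real_ else est$efficiency_mult
      out$r2 <- if (is.null(est)) NA_real_ else est$r_squared
    }
    out
  })
  do.call(rbind, rows)
}

empty_calls_df <- function() {
  data.frame(strain = character(), status = character(),
             fold_goi = numeric(), fold_goi_rounded = integer(),
             fold_cp = numeric(), fold_cp_rounded = integer(),
             p_vs_nuc = numeric(), p_vs_cp = numeric(),
             tie_break_used = logical(), note = character(),
             stringsAsFactors = FALSE)
}

call_to_row <- function(strain, call, note = NA_character_) {
  if (is.null(call))
    return(data.frame(strain = strain, status = NA_character_,
                      fold_goi = NA_real_, fold_goi_rounded = NA_integer_,
                      fold_cp = NA_real_, fold_cp_rounded = NA_integer_,
                      p_vs_nuc = NA_real_, p_vs_cp = NA_real_,
                      tie_break_used = NA, note = note,
                      stringsAsFactors = FALSE))
  data.frame(strain = strain, status = call$status,
             fold_goi = call$fold_goi$fold,
             fold_goi_rounded = call$fold_goi$fold_rounded,
             fold_cp = call$fold_cp$fold,
             fold_cp_rounded = call$fold_cp$fold_rounded,
             p_vs_nuc = call$p_vs_nuc, p_vs_cp = call$p_vs_cp,
             tie_break_used = call$tie_break_used, note = note,
             stringsAsFactors = FALSE)
}

run_localization_summary <- function(df, alpha, goi, nuclear_ref, plastid_ref) {
  strains <- sort(unique(df$strain))
  rows <- lapply(strains, function(st) {
    sub <- df[df$strain == st, , drop = FALSE]
    pick <- function(g) {
      r <- sub[sub$gene == g, , drop = FALSE]
      if (!nrow(r)) return(NULL)
      gene_summary(st, g, r$mean_ct[1], r$sd_ct[1], ifelse(is.na(r$n[1]), 0L, r$n[1]))
    }
    s_goi <- pick(goi); s_nuc <- pick(nuclear_ref); s_cp <- pick(plastid_ref)
    if (is.null(s_goi) || is.null(s_nuc) || is.null(s_cp))
      return(call_to_row(st, NULL, "REFERENCE_MISSING"))
    p_nuc <- sub$p_value[sub$gene == nuclear_ref][1]
    p_cp <- sub$p_value[sub$gene == plastid_ref][1]
    res <- tryCatch(
      suppressWarnings(classify_strain(
        s_goi, s_nuc, s_cp, alpha = alpha,
        p_vs_nuc = if (!is.na(p_nuc)) p_nuc else NULL,
        p_vs_cp = if (!is.na(p_cp)) p_cp else NULL)),
      petfloc_error = function(e) conditionMessage(e))
    if (is.character(res)) call_to_row(st, NULL, res) else call_to_row(st, res)
  })
  do.call(rbind, rows)
}

run_localization_ct <- function(df, alpha, goi, nuclear_ref, plastid_ref) {
  strains <- sort(unique(df$strain))
  rows <- lapply(strains, function(st) {
    sub <- df[df$strain == st, , drop = FALSE]
    cts <- function(g) {
      r <- sub[sub$gene == g, , drop = FALSE]
      if (!nrow(r)) return(NULL)
      r[order(r$bio_rep, r$tech_rep), , drop = FALSE]
    }
    r_goi <- cts(goi); r_nuc <- cts(nuclear_ref); r_cp <- cts(plastid_ref)
    if (is.null(r_goi) || is.null(r_nuc) || is.null(r_cp))
      return(call_to_row(st, NULL, "REFERENCE_MISSING"))
    s_goi <- summarize_ct(r_goi$ct, st, goi)
    s_nuc <- summarize_ct(r_nuc$ct, st, nuclear_ref)
    s_cp <- summarize_ct(r_cp$ct, st, plastid_ref)
    p_nuc <- p_cp <- NULL
    if (!s_goi$no_amplification && !s_nuc$no_amplification &&
        nrow(r_goi) == nrow(r_nuc) && nrow(r_goi) == nrow(r_cp)) {
      p_nuc <- tryCatch(compare_genes(r_goi$ct, r_nuc$ct)$p_value,
                        petfloc_error = function(e) NULL)
      p_cp <- tryCatch(compare_genes(r_goi$ct, r_cp$ct)$p_value,
                       petfloc_error = function(e) NULL)
    }
    res <- tryCatch(
      suppressWarnings(classify_strain(s_goi, s_nuc, s_cp, alpha = alpha,
                                       p_vs_nuc = p_nuc, p_vs_cp = p_cp)),
      petfloc_error = function(e) conditionMessage(e))
    if (is.character(res)) call_to_row(st, NULL, res) else call_to_row(st, res)
  })
  do.call(rbind, rows)
}
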