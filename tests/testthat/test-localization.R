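# Replicate aggregation, gene comparisons, and the compartment classifier

test_that("replicate summaries use the sample SD and flow sentinels", {
  s <- summarize_ct(rep(18.2, 6), "S", "petF")
  expect_equal(s$mean_ct, 18.2)
  expect_equal(s$sd_ct, 0)
  expect_equal(s$n, 6L)
  s2 <- summarize_ct(c(18.0, 18.4))
  expect_equal(s2$mean_ct, 18.2)
  expect_equal(s2$sd_ct, sd(c(18.0, 18.4)))
  expect_equal(s2$n, 2L)
  # all wells failed -> no-amplification sentinel, not an error
  s3 <- summarize_ct(c(NA_real_, NA_real_))
  expect_true(s3$no_amplification)
  expect_equal(s3$n, 0L)
  # crossed calls only are aggregated
  expect_equal(summarize_ct(c(10, NA, 12))$n, 2L)
})

test_that("Welch-from-summary p-values match an independent construction", {
  # oracle: rescale arbitrary samples to the exact summary moments, then
  # run stats::t.test on the samples themselves
  make_sample <- function(m, s, n, seed) {
    z <- withr::with_seed(seed, rnorm(n))
    m + s * (z - mean(z)) / sd(z)
  }
  withr::with_seed(42, {
    for (i in 1:50) {
      m1 <- runif(1, 10, 25); m2 <- runif(1, 10, 25)
      s1 <- runif(1, 0.05, 1.5); s2 <- runif(1, 0.05, 1.5)
      n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
      got <- welch_from_summary(m1, s1, n1, m2, s2, n2)
      tt <- t.test(make_sample(m1, s1, n1, i), make_sample(m2, s2, n2, 1000 + i))
      expect_equal(got$p_value, tt$p.value, tolerance = 1e-10)
      expect_equal(got$statistic, unname(tt$statistic), tolerance = 1e-10)
      expect_equal(got$df, unname(tt$parameter), tolerance = 1e-8)
    }
  })
  # the spec-level worked pair
  got <- welch_from_summary(19.6, 0.3, 6, 18.8, 0.1, 6)
  expect_equal(got$statistic, 0.8 / sqrt(0.09 / 6 + 0.01 / 6), tolerance = 1e-12)
  expect_equal(got$method, "welch_from_summary")
})

test_that("paired comparisons handle degenerate replicate structures", {
  r <- compare_genes(c(10, 11, 12), c(10, 11, 12))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  r2 <- compare_genes(c(10, 11, 12), c(11, 12, 13))  # constant difference -1
  expect_true(r2$degenerate)
  expect_equal(r2$p_value, 0)
  r3 <- compare_genes(c(10.1, 11.3, 12.2), c(11.0, 12.4, 13.1))
  expect_equal(r3$method, "paired")
  expect_equal(r3$p_value,
               t.test(c(10.1, 11.3, 12.2), c(11.0, 12.4, 13.1),
                      paired = TRUE)$p.value)
  expect_error(compare_genes(10, 11), class = "petfloc_insufficient_replicates")
})

test_that("classifier applies the dual-reference decision rule", {
  gs <- function(g, m, s) gene_summary("S", g, m, s, 6L)
  # non-significant vs nuclear, significant vs plastid -> nuclear transfer
  call <- classify_strain(gs("petF", 18.8, 0.1), gs("tef1a", 19.6, 0.3),
                          gs("rbcS", 14.3, 0.0),
                          p_vs_nuc = 1.04e-2, p_vs_cp = 3.20e-8)
  expect_equal(call$status, "NUCLEAR_TRANSFER")
  expect_false(call$tie_break_used)
  # both significant -> magnitude tie-break on log2 scale (plastid case)
  call2 <- classify_strain(gs("petF", 11.2, 0.2), gs("tef1a", 19.2, 0.2),
                           gs("rbcS", 12.1, 0.3),
                           p_vs_nuc = 1.23e-13, p_vs_cp = 9.09e-7)
  expect_equal(call2$status, "PLASTID_RETENTION")
  expect_true(call2$tie_break_used)
  # both significant, gene of interest nearer the nuclear copy number
  call3 <- classify_strain(gs("petF", 18.2, 0.1), gs("tef1a", 19.2, 0.5),
                           gs("rbcS", 14.6, 0.1),
                           p_vs_nuc = 4.64e-3, p_vs_cp = 2.12e-9)
  expect_equal(call3$status, "NUCLEAR_TRANSFER")
  expect_true(call3$tie_break_used)
  # gene of interest never amplified -> UNKNOWN
  call4 <- classify_strain(gene_summary("S", "petF", NA, NA, 0),
                           gs("tef1a", 19.2, 0.5), gs("rbcS", 14.6, 0.1))
  expect_equal(call4$status, "UNKNOWN")
  # plastid reference not enriched over nuclear -> QC failure
  expect_error(classify_strain(gs("petF", 18, 0.1), gs("tef1a", 19, 0.1),
                               gs("rbcS", 20, 0.1)),
               class = "petfloc_reference_qc_failure")
  # neither comparison significant -> AMBIGUOUS with a warning
  expect_warning(
    call5 <- classify_strain(gs("petF", 18.9, 0.4), gs("tef1a", 19, 0.4),
                             gs("rbcS", 18.5, 0.4),
                             p_vs_nuc = 0.5, p_vs_cp = 0.2),
    class = "petfloc_reference_qc")
  expect_equal(call5$status, "AMBIGUOUS")
})

test_that("tie-break assigns the gene to the reference with the nearer copy number", {
  withr::with_seed(7, {
    for (i in 1:20) {
      m_nuc <- runif(1, 17, 22)
      fold_cp <- runif(1, 8, 200)
      fold_goi <- if (i %% 2) runif(1, 0.8, 2) else fold_cp * runif(1, 0.8, 1.2)
      gs <- function(g, m) gene_summary("S", g, m, 0.1, 6L)
      s_goi <- gs("petF", m_nuc - log2(fold_goi))
      s_nuc <- gs("tef1a", m_nuc)
      s_cp <- gs("rbcS", m_nuc - log2(fold_cp))
      a <- classify_strain(s_goi, s_nuc, s_cp, p_vs_nuc = 1e-4, p_vs_cp = 1e-4)
      expect_true(a$tie_break_used)
      # independent computation of the two log2 distances; consistency here
      # implies the call flips if the two reference roles are interchanged,
      # because the distances simply swap
      d_nuc <- abs(log2(fold_goi))
      d_cp <- abs(log2(fold_goi) - log2(fold_cp))
      expected <- if (d_nuc < d_cp) "NUCLEAR_TRANSFER"
                  else if (d_cp < d_nuc) "PLASTID_RETENTION" else "AMBIGUOUS"
      expect_equal(a$status, expected)
    }
  })
})

test_that("whole-table localization reproduces the published strain calls", {
  calls <- run_localization(read_summary_csv(summary_fixture_path()))
  expect_equal(nrow(calls), 12L)
  expect_equal(calls$strain, sort(calls$strain))  # deterministic ordering
  nuclear <- calls$strain[calls$status == "NUCLEAR_TRANSFER" & !is.na(calls$status)]
  expect_setequal(nuclear, c("CCMP0999", "CCMP1001", "CCMP1005", "CCMP1006"))
  expect_equal(sum(calls$status == "PLASTID_RETENTION", na.rm = TRUE), 7L)
  expect_equal(calls$status[calls$strain == "CCMP1616"], "UNKNOWN")
})

test_that("empty and incomplete tables degrade gracefully", {
  empty <- run_localization(data.frame(strain = character(), gene = character(),
                                       mean_ct = numeric(), sd_ct = numeric(),
                                       n = integer(), p_value = numeric()))
  expect_equal(nrow(empty), 0L)
  # a strain missing a reference gene is reported, others still processed
  df <- read_summary_csv(summary_fixture_path())
  df <- df[!(df$strain == "CCMP1005" & df$gene == "rbcS"), ]
  calls <- run_localization(df)
  expect_equal(calls$note[calls$strain == "CCMP1005"], "REFERENCE_MISSING")
  expect_equal(calls$status[calls$strain == "CCMP1006"], "NUCLEAR_TRANSFER")
})

test_that("classifier recovers simulated ground truth on noisy plates", {
  n_ok <- 0L; n_total <- 0L
  for (rep in 1:200) {
    strains <- data.frame(
      strain_id = c("N1", "N2", "P1", "P2"),
      true_localization = c("nuclear", "nuclear", "plastid", "plastid"),
      plastid_genomes_per_cell = withr::with_seed(5000 + rep,
        round(runif(4, 20, 200))))
    sim <- simulate_plate(strains, ct_noise_sd = 0.5, seed = 9000 + rep)
    calls <- suppressWarnings(run_localization(sim$ct_table))
    truth <- ifelse(strains$true_localization == "nuclear",
                    "NUCLEAR_TRANSFER", "PLASTID_RETENTION")
    got <- calls$status[match(strains$strain_id, calls$strain)]
    n_ok <- n_ok + sum(got == truth, na.rm = TRUE)
    n_total <- n_total + length(truth)
  }
  expect_gte(n_ok / n_total, 0.95)
})
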