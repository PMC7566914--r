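#' Simulate one qPCR amplification curve
#'
#' Logistic-plateau exponential model: fluorescence at cycle c is
#' `baseline + min(N0 * E^c, plateau) * (1 + eps_c)` with
#' `eps_c ~ Normal(0, mult_noise_sd)`. With no noise the curve crosses any
#' threshold `T` in `(0, plateau)` exactly at cycle `log_E(T / N0)`, which
#' is the closed-form oracle the Ct caller is tested against.
#'
#' @param N0 starting template amount in fluorescence units (must be below
#'   `plateau`).
#' @param baseline constant background fluorescence (default 0.05).
#' @param efficiency_mult per-cycle fold increase E in (1, 2] (default 2,
#'   perfect doubling).
#' @param plateau saturation fluorescence (default 2).
#' @param mult_noise_sd multiplicative noise SD (default 0).
#' @param n_cycles number of cycles (default 40).
#' @param seed optional RNG seed (restores RNG state afterwards).
#' @param well_id,strain_id,gene_id,bio_replicate,tech_replicate labels for
#'   the resulting curve.
#' @return An [amp_curve].
#' @export
simulate_curve <- function(N0, baseline = 0.05, efficiency_mult = 2,
                           plateau = 2, mult_noise_sd = 0, n_cycles = 40L,
                           seed = NULL, well_id = "sim", strain_id = "sim",
                           gene_id = "sim", bio_replicate = 1L,
                           tech_replicate = 1L) {
  if (!is.numeric(N0) || N0 <= 0) stop_petfloc("parameter", "N0 must be > 0")
  if (N0 >= plateau) stop_petfloc("parameter", "N0 must be below the plateau")
  if (efficiency_mult <= 1 || efficiency_mult > 2)
    stop_petfloc("parameter", "efficiency_mult must be in (1, 2]")
  if (plateau <= baseline) stop_petfloc("parameter", "plateau must exceed baseline")
  if (n_cycles < 20L) stop_petfloc("parameter", "need n_cycles >= 20")
  with_seed(seed, {
    cyc <- seq_len(n_cycles)
    signal <- pmin(N0 * efficiency_mult^cyc, plateau)
    eps <- if (mult_noise_sd > 0) stats::rnorm(n_cycles, 0, mult_noise_sd) else 0
    amp_curve(well_id, strain_id, gene_id, bio_replicate, tech_replicate,
              cyc, baseline + signal * (1 + eps))
  })
}

#' Simulate a whole qPCR plate with known ground truth
#'
#' Encodes the dual-reference copy-number logic: the nuclear reference
#' (tef1a) sits at 1 relative copy, the plastid reference (rbcS) at the
#' strain's plastid genome copies per cell, and the gene of interest
#' (petF) at 1 if its true compartment is nuclear or at the plastid copy
#' number if plastid-retained. Each well's Ct is
#' `ct_ref_nuclear - log2(relative copies) + Normal(0, ct_noise_sd)`
#' (plus an optional per-biological-replicate shift). Wells listed in
#' `failed` never amplify (`ct = NA`), modelling primer failure.
#'
#' @param strains data.frame with columns `strain_id`,
#'   `true_localization` (`"nuclear"`/`"plastid"`) and
#'   `plastid_genomes_per_cell` (integer, at least 2).
#' @param ct_ref_nuclear baseline Ct of a single-copy nuclear gene
#'   (default 20).
#' @param ct_noise_sd per-well Ct noise SD (default 0.3).
#' @param sd_bio additive between-biological-replicate Ct shift SD
#'   (default 0).
#' @param n_bio,n_tech biological and technical replicates (defaults 2
#'   and 3: triplicates of two independent biological samples).
#' @param genes gene labels in the order (gene of interest, nuclear
#'   reference, plastid reference).
#' @param failed optional data.frame `strain,gene` of wells that must not
#'   amplify.
#' @param level `"ct"` returns a replicate-level Ct table; `"curve"`
#'   additionally returns full fluorescence curves whose noiseless Ct
#'   matches the drawn Ct.
#' @param curve_params list passed to [simulate_curve] (baseline,
#'   efficiency_mult, plateau, mult_noise_sd, n_cycles).
#' @param threshold threshold used to back-compute N0 for curve-level
#'   simulation (default 0.2).
#' @param seed RNG seed.
#' @return A list with `ct_table`
#'   (`strain,gene,bio_rep,tech_rep,ct`), `truth` (the `strains` input),
#'   and, when `level = "curve"`, `curves` (a list of [amp_curve]).
#' @export
simulate_plate <- function(strains, ct_ref_nuclear = 20, ct_noise_sd = 0.3,
                           sd_bio = 0, n_bio = 2L, n_tech = 3L,
                           genes = c("petF", "tef1a", "rbcS"),
                           failed = NULL, level = c("ct", "curve"),
                           curve_params = list(), threshold = 0.2,
                           seed = NULL) {
  level <- match.arg(level)
  stopifnot(is.data.frame(strains),
            all(c("strain_id", "true_localization",
                  "plastid_genomes_per_cell") %in% names(strains)))
  if (any(strains$plastid_genomes_per_cell < 2))
    stop_petfloc("parameter", "plastid_genomes_per_cell must be >= 2")
  if (n_bio * n_tech < 2L)
    stop_petfloc("parameter", "need at least 2 replicate wells")
  if (!all(strains$true_localization %in% c("nuclear", "plastid")))
    stop_petfloc("parameter", "true_localization must be nuclear or plastid")
  with_seed(seed, {
    rows <- list(); curves <- list(); w <- 0L
    for (i in seq_len(nrow(strains))) {
      st <- strains$strain_id[i]
      P <- strains$plastid_genomes_per_cell[i]
      copies <- c(if (strains$true_localization[i] == "nuclear") 1 else P, 1, P)
      names(copies) <- genes
      for (g in genes) {
        is_failed <- !is.null(failed) &&
          any(failed$strain == st & failed$gene == g)
        for (b in seq_len(n_bio)) {
          bio_shift <- if (sd_bio > 0) stats::rnorm(1, 0, sd_bio) else 0
          for (tch in seq_len(n_tech)) {
            w <- w + 1L
            ct <- if (is_failed) NA_real_ else
              ct_ref_nuclear - log2(copies[[g]]) + bio_shift +
                (if (ct_noise_sd > 0) stats::rnorm(1, 0, ct_noise_sd) else 0)
            rows[[w]] <- data.frame(well = sprintf("W%03d", w), strain = st,
                                    gene = g, bio_rep = b, tech_rep = tch,
                                    ct = ct, stringsAsFactors = FALSE)
            if (level == "curve") {
              cp <- utils::modifyList(
                list(baseline = 0.05, efficiency_mult = 2, plateau = 2,
                     mult_noise_sd = 0, n_cycles = 40L), curve_params)
              curves[[w]] <- if (is_failed) {
                # flat background: never crosses any positive threshold
                amp_curve(sprintf("W%03d", w), st, g, b, tch,
                          seq_len(cp$n_cycles),
                          rep(cp$baseline, cp$n_cycles) *
                            (1 + stats::rnorm(cp$n_cycles, 0, cp$mult_noise_sd)))
              } else {
                N0 <- threshold * cp$efficiency_mult^(-ct)
                simulate_curve(N0, baseline = cp$baseline,
                               efficiency_mult = cp$efficiency_mult,
                               plateau = cp$plateau,
                               mult_noise_sd = cp$mult_noise_sd,
                               n_cycles = cp$n_cycles,
                               well_id = sprintf("W%03d", w), strain_id = st,
                               gene_id = g, bio_replicate = b,
                               tech_replicate = tch)
              }
            }
          }
        }
      }
    }
    out <- list(ct_table = do.call(rbind, rows), truth = strains)
    if (level == "curve") out$curves <- curves
    out
  })
}

#' Simulate Sanger reads tiled over a template
#'
#' Reads of fixed length are sampled at evenly spaced offsets covering the
#' template, with independent per-base substitution errors and optional
#' strand flipping. The tiling is checked to guarantee that consecutive
#' reads overlap by at least `min_overlap`, so an error-free read set is
#' assemblable by construction.
#'
#' @param template nucleotide string.
#' @param n_reads number of reads (at least 1).
#' @param read_len read length (at most the template length).
#' @param substitution_rate per-base substitution probability (default 0).
#' @param revcomp_prob probability that a read is reverse-complemented
#'   (default 0).
#' @param min_overlap required overlap between consecutive reads
#'   (default 30).
#' @param seed RNG seed.
#' @return Named character vector of reads (`read1`, `read2`, ...), with
#'   attribute `offsets` (1-based template start of each read).
#' @export
simulate_sanger_reads <- function(template, n_reads, read_len,
                                  substitution_rate = 0, revcomp_prob = 0,
                                  min_overlap = 30L, seed = NULL) {
  template <- toupper(as.character(template))
  L <- nchar(template)
  if (read_len > L) stop_petfloc("parameter", "read_len exceeds template length")
  if (n_reads < 1L) stop_petfloc("parameter", "need at least one read")
  offsets <- if (n_reads == 1L) 1L
             else round(seq(1L, L - read_len + 1L, length.out = n_reads))
  if (n_reads > 1L) {
    gaps <- diff(offsets)
    if (length(gaps) && any(read_len - gaps < min_overlap))
      stop_petfloc("parameter",
                   sprintf("tiling infeasible: consecutive overlap %d < min_overlap %d",
                           read_len - max(gaps), min_overlap))
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    reads <- vapply(offsets, function(o) {
      r <- strsplit(substr(template, o, o + read_len - 1L), "", fixed = TRUE)[[1]]
      if (substitution_rate > 0) {
        hit <- which(stats::runif(read_len) < substitution_rate)
        for (h in hit) r[h] <- sample(setdiff(bases, r[h]), 1L)
      }
      s <- paste(r, collapse = "")
      if (revcomp_prob > 0 && stats::runif(1) < revcomp_prob) s <- revcomp(s)
      s
    }, "")
    names(reads) <- paste0("read", seq_along(reads))
    attr(reads, "offsets") <- offsets
    reads
  })
}

#' Simulate irreversible loss of a plastid-encoded gene on a tree
#'
#' The root's ancestor is PRESENT; walking from the root towards the tips,
#' each edge below a PRESENT node flips to ABSENT with probability
#' `loss_prob_per_edge`; ABSENT is absorbing. Returns the realized tip
#' states together with the true number of loss events, which upper-bounds
#' what [min_transfer_events] can recover.
#'
#' @param tree a rooted [ape::phylo] tree.
#' @param loss_prob_per_edge probability of loss on each edge, in [0, 1].
#' @param seed RNG seed.
#' @return A list with `states` (named character, per tip),
#'   `true_event_count` and `event_edges` (row indices of `tree$edge`
#'   where losses occurred).
#' @export
simulate_loss_states <- function(tree, loss_prob_per_edge, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (loss_prob_per_edge < 0 || loss_prob_per_edge > 1)
    stop_petfloc("parameter", "loss_prob_per_edge must be in [0, 1]")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  with_seed(seed, {
    present <- rep(NA, nnode)
    present[root] <- TRUE
    # preorder: parents before children
    eord <- order(tree$edge[, 1])
    # BFS from root
    queue <- root
    events <- integer(0)
    while (length(queue)) {
      nd <- queue[1]; queue <- queue[-1]
      eidx <- which(tree$edge[, 1] == nd)
      for (e in eidx) {
        chd <- tree$edge[e, 2]
        if (!present[nd]) {
          present[chd] <- FALSE
        } else if (stats::runif(1) < loss_prob_per_edge) {
          present[chd] <- FALSE
          events <- c(events, e)
        } else {
          present[chd] <- TRUE
        }
        if (chd > ntip) queue <- c(queue, chd)
      }
    }
    list(states = stats::setNames(ifelse(present[seq_len(ntip)],
                                         "present", "absent"),
                                  tree$tip.label),
         true_event_count = length(events),
         event_edges = events)
  })
}
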