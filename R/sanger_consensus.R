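#' @importFrom methods as is
#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   reverseComplement pairwiseAlignment readDNAStringSet readAAStringSet
#'   writeXStringSet subseq translate
NULL

# default alignment scoring (documented configuration, BLAST-like)
nt_submat <- function(match = 2, mismatch = -3)
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE)

aa_submat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

revcomp <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Extract the best-hit aligned region of a read
#'
#' Aligns a read against a set of reference sequences by local pairwise
#' alignment (affine gaps) and returns the query interval of the best
#' significant hit. Nucleotide mode scores the read and its reverse
#' complement directly against nucleotide references (match +2, mismatch
#' -3, gap open 5 / extend 2). Translated mode translates the read in all
#' six frames and scores each translation against protein references
#' (BLOSUM62, gap open 11 / extend 1), for loci where the references are
#' proteins. Significance is a raw-score cutoff calibrated so random reads
#' essentially never pass.
#'
#' @param read nucleotide string (or `DNAString`).
#' @param references named character vector / `XStringSet`: nucleotide
#'   sequences in `"nucleotide"` mode, protein sequences in `"translated"`
#'   mode.
#' @param mode `"nucleotide"` or `"translated"`.
#' @param score_threshold minimum alignment score for a significant hit
#'   (default 40 nucleotide, 50 translated).
#' @return A list of class `hit_region` with `q_start`, `q_end` (0-based
#'   half-open on the read as given), `ref_id`, `score`, `strand`,
#'   `frame` (translated mode), `significant = TRUE`; or `NULL` when no
#'   alignment reaches the threshold (no hit).
#' @export
extract_best_hit_region <- function(read, references,
                                    mode = c("nucleotide", "translated"),
                                    score_threshold = NULL) {
  mode <- match.arg(mode)
  read <- toupper(as.character(read))
  if (!nzchar(read)) stop_petfloc("input", "empty read")
  refs <- as.character(references)
  if (!length(refs)) stop_petfloc("input", "empty reference set")
  if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
  if (is.null(score_threshold))
    score_threshold <- if (mode == "nucleotide") 40 else 50
  n <- nchar(read)
  best <- NULL
  consider <- function(cand) {
    # ties: higher score wins; then lower reference index, then leftmost start
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score &&
         (cand$ref_i < best$ref_i ||
          (cand$ref_i == best$ref_i && cand$q_start < best$q_start))))
      best <<- cand
  }
  if (mode == "nucleotide") {
    mat <- nt_submat()
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") read else revcomp(read)
      for (i in seq_along(refs)) {
        aln <- Biostrings::pairwiseAlignment(qseq, refs[[i]], type = "local",
                                             substitutionMatrix = mat,
                                             gapOpening = 5, gapExtension = 2)
        s <- Biostrings::score(aln)
        if (s < score_threshold) next
        qs <- methods::slot(aln, "pattern")@range@start
        qe <- qs + methods::slot(aln, "pattern")@range@width - 1L
        if (strand == "-") { tmp <- qs; qs <- n - qe + 1L; qe <- n - tmp + 1L }
        consider(list(q_start = qs - 1L, q_end = qe, ref_id = names(refs)[i],
                      ref_i = i, score = s, strand = strand, frame = NA_integer_))
      }
    }
  } else {
    mat <- aa_submat()
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") read else revcomp(read)
      for (off in 0:2) {
        alen <- (nchar(qseq) - off) %/% 3L
        if (alen < 1L) next
        codons <- substr(qseq, off + 1L, off + 3L * alen)
        aa <- as.character(suppressWarnings(
          Biostrings::translate(Biostrings::DNAString(codons),
                                if.fuzzy.codon = "X")))
        for (i in seq_along(refs)) {
          aln <- Biostrings::pairwiseAlignment(aa, refs[[i]], type = "local",
                                               substitutionMatrix = mat,
                                               gapOpening = 11, gapExtension = 1)
          s <- Biostrings::score(aln)
          if (s < score_threshold) next
          as1 <- methods::slot(aln, "pattern")@range@start
          ae1 <- as1 + methods::slot(aln, "pattern")@range@width - 1L
          qs <- off + 3L * (as1 - 1L) + 1L
          qe <- off + 3L * ae1
          if (strand == "-") { tmp <- qs; qs <- n - qe + 1L; qe <- n - tmp + 1L }
          consider(list(q_start = qs - 1L, q_end = qe, ref_id = names(refs)[i],
                        ref_i = i, score = s, strand = strand, frame = off))
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$ref_i <- NULL
  structure(c(best, list(significant = TRUE)), class = "hit_region")
}

# ---- greedy overlap-layout-consensus ----------------------------------

# best suffix(a)->prefix(b) ungapped overlap; returns matches and length,
# or NULL if nothing reaches min_overlap/min_identity
best_sp_overlap <- function(a, b, min_overlap, min_identity) {
  na <- nchar(a); nb <- nchar(b)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- NULL
  for (L in seq(min(na, nb), min_overlap)) {
    m <- sum(av[(na - L + 1L):na] == bv[1:L])
    if (m / L >= min_identity && (is.null(best) || m > best$matches))
      best <- list(len = L, matches = m)
  }
  best
}

rc_contig <- function(contig) {
  n <- nchar(contig$sequence)
  contig$sequence <- revcomp(contig$sequence)
  contig$members <- lapply(contig$members, function(mb) {
    mb$offset <- n - (mb$offset + nchar(mb$sequence))
    mb$sequence <- revcomp(mb$sequence)
    mb$strand <- if (mb$strand == "+") "-" else "+"
    mb
  })
  contig
}

consensus_from_members <- function(members, len) {
  out <- character(len)
  cover <- lapply(members, function(mb)
    list(start = mb$offset + 1L, chars = strsplit(mb$sequence, "", fixed = TRUE)[[1]],
         len = nchar(mb$sequence)))
  for (pos in seq_len(len)) {
    bases <- character(0); lens <- integer(0)
    for (cv in cover) {
      j <- pos - cv$start + 1L
      if (j >= 1L && j <= cv$len) { bases <- c(bases, cv$chars[j]); lens <- c(lens, cv$len) }
    }
    if (!length(bases)) { out[pos] <- "N"; next }
    tb <- table(bases)
    top <- names(tb)[tb == max(tb)]
    out[pos] <- if (length(top) == 1L) top
                else {
                  # tie broken toward the longest member read covering the column
                  ord <- order(-lens, bases)
                  bases[ord][match(TRUE, bases[ord] %in% top)]
                }
  }
  paste(out, collapse = "")
}

new_contig <- function(sequence, read_id) {
  list(sequence = sequence,
       members = list(list(read_id = read_id, offset = 0L,
                           strand = "+", sequence = sequence)))
}

#' Assemble reads into contigs by greedy overlap-layout-consensus
#'
#' Repeatedly merges the pair of contigs with the best qualifying
#' suffix-prefix overlap (length at least `min_overlap`, ungapped identity
#' at least `min_identity`, reverse-complement orientation allowed) until
#' no merge qualifies. The consensus is per-column majority over member
#' reads, ties broken toward the longest member covering the column.
#' Inputs are canonically sorted first so the result does not depend on
#' input order.
#'
#' @param reads named character vector (or `DNAStringSet`) of reads or
#'   extracted hit regions.
#' @param min_overlap minimum overlap length in nt (default 30).
#' @param min_identity minimum overlap identity (default 0.9).
#' @return A list of contigs; each contig is a list with `sequence` and
#'   `members` (read ids with offsets and strands).
#' @export
assemble <- function(reads, min_overlap = 30L, min_identity = 0.9) {
  reads <- toupper(as.character(reads))
  if (!length(reads)) stop_petfloc("input", "no reads to assemble")
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    names(reads) <- paste0("read", seq_along(reads))
  ord <- order(-nchar(reads), reads, names(reads))
  reads <- reads[ord]
  contigs <- mapply(new_contig, reads, names(reads),
                    SIMPLIFY = FALSE, USE.NAMES = FALSE)
  repeat {
    nc <- length(contigs)
    if (nc < 2L) break
    best <- NULL
    for (i in seq_len(nc - 1L)) for (j in seq(i + 1L, nc)) {
      for (flip in c(FALSE, TRUE)) {
        bseq <- if (flip) revcomp(contigs[[j]]$sequence) else contigs[[j]]$sequence
        for (ordr in 1:2) {
          a <- if (ordr == 1L) contigs[[i]]$sequence else bseq
          b <- if (ordr == 1L) bseq else contigs[[i]]$sequence
          ov <- best_sp_overlap(a, b, min_overlap, min_identity)
          if (!is.null(ov) && (is.null(best) || ov$matches > best$matches))
            best <- list(i = i, j = j, flip = flip, ordr = ordr,
                         len = ov$len, matches = ov$matches)
        }
      }
    }
    if (is.null(best)) break
    ca <- contigs[[best$i]]
    cb <- contigs[[best$j]]
    if (best$flip) cb <- rc_contig(cb)
    if (best$ordr == 2L) { tmp <- ca; ca <- cb; cb <- tmp }
    shift <- nchar(ca$sequence) - best$len
    cb$members <- lapply(cb$members, function(mb) { mb$offset <- mb$offset + shift; mb })
    members <- c(ca$members, cb$members)
    len <- max(vapply(members, function(mb) mb$offset + nchar(mb$sequence), 1L))
    merged <- list(sequence = consensus_from_members(members, len), members = members)
    contigs <- c(contigs[-c(best$i, best$j)], list(merged))
  }
  contigs
}

#' Pick the representative contig
#'
#' Among contigs with a significant hit to any reference, returns the
#' longest; ties are broken lexicographically by sequence so the choice is
#' deterministic.
#'
#' @param contigs list of contigs from [assemble] (or a character vector of
#'   sequences).
#' @param references reference sequences (see [extract_best_hit_region]).
#' @param mode,score_threshold passed to [extract_best_hit_region].
#' @return The chosen contig (errors with class
#'   `petfloc_no_representative` when none is similar to any reference).
#' @export
pick_representative <- function(contigs, references,
                                mode = c("nucleotide", "translated"),
                                score_threshold = NULL) {
  mode <- match.arg(mode)
  if (is.character(contigs)) contigs <- lapply(unname(contigs), new_contig, read_id = "contig")
  seqs <- vapply(contigs, `[[`, "", "sequence")
  ok <- vapply(seqs, function(s)
    !is.null(extract_best_hit_region(s, references, mode, score_threshold)),
    logical(1))
  if (!any(ok))
    stop_petfloc("no_representative", "no contig is similar to any reference")
  cand <- which(ok)
  cand <- cand[order(-nchar(seqs[cand]), seqs[cand])]
  contigs[[cand[1L]]]
}

#' Determine the reading frame and translate
#'
#' Translates a nucleotide sequence in all six frames (standard code,
#' internal stops rendered `*`) and picks the frame whose translation has
#' the best-scoring local alignment (BLOSUM62) to any protein reference.
#'
#' @param nt nucleotide string, length at least 60.
#' @param protein_references named character vector / `AAStringSet`.
#' @param score_threshold minimum significant protein score (default 50).
#' @return A list with `frame` (0, 1 or 2), `strand` (`"+"`/`"-"`), `aa`
#'   (the full translation of the chosen frame), `score` and `ref_id`.
#'   Errors with class `petfloc_frame_undetermined` when no frame has a
#'   significant hit.
#' @export
translate_in_frame <- function(nt, protein_references, score_threshold = 50) {
  nt <- toupper(as.character(nt))
  if (nchar(nt) < 60L) stop_petfloc("input", "need >= 60 nt to call a reading frame")
  refs <- as.character(protein_references)
  if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
  mat <- aa_submat()
  best <- NULL
  for (strand in c("+", "-")) {
    qseq <- if (strand == "+") nt else revcomp(nt)
    for (off in 0:2) {
      alen <- (nchar(qseq) - off) %/% 3L
      if (alen < 1L) next
      codons <- substr(qseq, off + 1L, off + 3L * alen)
      aa <- as.character(suppressWarnings(
        Biostrings::translate(Biostrings::DNAString(codons), if.fuzzy.codon = "X")))
      for (i in seq_along(refs)) {
        s <- Biostrings::score(
          Biostrings::pairwiseAlignment(aa, refs[[i]], type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 11, gapExtension = 1))
        if (s >= score_threshold && (is.null(best) || s > best$score))
          best <- list(frame = off, strand = strand, aa = aa, score = s,
                       ref_id = names(refs)[i])
      }
    }
  }
  if (is.null(best))
    stop_petfloc("frame_undetermined", "no reading frame with a significant protein hit")
  best
}

#' Trim a translated protein to publication form
#'
#' Removes leading residues up to the first methionine when the sequence
#' does not already start with `M` (and, when a reference length is given,
#' only if the sequence is longer than that reference -- over-length
#' N-termini are the signature of mispredicted starts), and removes a
#' single trailing `X` residue.
#'
#' @param aa protein string.
#' @param reference_length optional full length of the homologous
#'   reference protein.
#' @return A list with `aa`, `trimmed_leading`, `trimmed_trailing_X` and
#'   `trim_failed` (`TRUE` when leading trimming applied but the sequence
#'   has no `M`; the sequence is then returned untrimmed at the start).
#' @export
trim_protein <- function(aa, reference_length = NULL) {
  aa <- toupper(as.character(aa))
  if (!nzchar(aa)) stop_petfloc("input", "empty protein sequence")
  trimmed_leading <- 0L
  trim_failed <- FALSE
  if (substr(aa, 1, 1) != "M" &&
      (is.null(reference_length) || nchar(aa) > reference_length)) {
    m <- regexpr("M", aa, fixed = TRUE)
    if (m < 0) {
      trim_failed <- TRUE
    } else {
      trimmed_leading <- as.integer(m) - 1L
      aa <- substr(aa, m, nchar(aa))
    }
  }
  trimmed_trailing_X <- 0L
  if (nchar(aa) > 1L && substr(aa, nchar(aa), nchar(aa)) == "X") {
    aa <- substr(aa, 1L, nchar(aa) - 1L)
    trimmed_trailing_X <- 1L
  }
  list(aa = aa, trimmed_leading = trimmed_leading,
       trimmed_trailing_X = trimmed_trailing_X, trim_failed = trim_failed)
}

#' Build the representative sequence for one strain and locus
#'
#' Runs the whole Sanger post-processing chain: best-hit region extraction
#' per read, greedy assembly of the extracted regions, choice of the
#' longest reference-similar contig, and (for protein-coding loci, when
#' protein references are supplied) reading-frame translation plus
#' N-terminal Met / trailing-X trimming.
#'
#' @param reads named character vector (or `DNAStringSet`) of Sanger reads.
#' @param references nucleotide references (nucleotide mode) or protein
#'   references (translated mode) used for region extraction and
#'   representative choice.
#' @param mode `"nucleotide"` or `"translated"` (see
#'   [extract_best_hit_region]).
#' @param protein_references protein references for frame determination;
#'   defaults to `references` in translated mode.
#' @param strain_id,locus labels carried on the result.
#' @param min_overlap,min_identity assembler parameters.
#' @param score_threshold significance cutoff for hits.
#' @return A list of class `representative_sequence` with `strain_id`,
#'   `locus`, `nt`, and for translated loci `frame`, `strand`, `aa`,
#'   `trimmed_leading`, `trimmed_trailing_X`.
#' @export
sanger_representative <- function(reads, references,
                                  mode = c("nucleotide", "translated"),
                                  protein_references = NULL,
                                  strain_id = NA_character_, locus = NA_character_,
                                  min_overlap = 30L, min_identity = 0.9,
                                  score_threshold = NULL) {
  mode <- match.arg(mode)
  reads <- toupper(as.character(reads))
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  regions <- character(0)
  for (i in seq_along(reads)) {
    hit <- extract_best_hit_region(reads[[i]], references, mode, score_threshold)
    if (is.null(hit)) next
    regions[names(reads)[i]] <- substr(reads[[i]], hit$q_start + 1L, hit$q_end)
  }
  if (!length(regions))
    stop_petfloc("no_representative", "no read has a significant hit to the references")
  contigs <- assemble(regions, min_overlap = min_overlap, min_identity = min_identity)
  rep <- pick_representative(contigs, references, mode, score_threshold)
  out <- list(strain_id = strain_id, locus = locus, nt = rep$sequence,
              n_reads_used = length(rep$members))
  if (mode == "translated") {
    prefs <- if (is.null(protein_references)) references else protein_references
    tr <- translate_in_frame(rep$sequence, prefs,
                             score_threshold = if (is.null(score_threshold)) 50 else score_threshold)
    trm <- trim_protein(tr$aa)
    out$frame <- tr$frame; out$strand <- tr$strand
    out$aa <- trm$aa
    out$trimmed_leading <- trm$trimmed_leading
    out$trimmed_trailing_X <- trm$trimmed_trailing_X
  }
  structure(out, class = "representative_sequence")
}

#' Read / write FASTA as named character vectors
#'
#' Thin wrappers around Biostrings readers for the package's plain
#' sequence-in / sequence-out interfaces. Headers of the form
#' `strain|locus|read` are carried as names.
#'
#' @param path file path.
#' @param type `"dna"` or `"protein"`.
#' @return `read_fasta`: a named character vector.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
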