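# shared fixture builders; everything is generated in code, seeded by the
# caller

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# back-translate a protein with fixed codons (round-trip fixture)
back_translate <- function(aa) {
  codons <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
              E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
              M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
              Y = "TAT", V = "GTT")
  paste(codons[strsplit(aa, "", fixed = TRUE)[[1]]], collapse = "")
}

# a ferredoxin-like reference protein used across sanger tests
fdx_ref <- c(fdx = paste0("MATYKVTLKTPSGDKTIECPDDTYILDAAEEAGLDLPYSCRAGACSTC",
                          "AGKLVSGTVDQSDQSFLDDDQIEAGYVLTCVAYPTSDVVIETHKEEDLY"))

# random rooted binary tree with branch lengths, via ape
random_tree <- function(ntip, lengths = TRUE) {
  tr <- ape::rtree(ntip, rooted = TRUE)
  if (!lengths) tr$edge.length <- NULL
  tr
}

# write a long-format plate CSV for a list of amp_curve objects
write_plate_csv <- function(curves, path) {
  rows <- do.call(rbind, lapply(curves, function(cv)
    data.frame(well = cv$well_id, strain = cv$strain_id, gene = cv$gene_id,
               bio_rep = cv$bio_replicate, tech_rep = cv$tech_replicate,
               cycle = cv$cycles, fluorescence = cv$fluorescence)))
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

summary_fixture_path <- function()
  system.file("extdata", "thalassiosira_petf_ct_summary.csv", package = "petfloc")

scenario_fixture <- function() {
  list(tree = parse_newick(system.file("extdata",
         "stramenopile_classes_synthetic.nwk", package = "petfloc")),
       states = read_states_tsv(system.file("extdata",
         "stramenopile_petf_states_synthetic.tsv", package = "petfloc")))
}
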