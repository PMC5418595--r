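# Shared fixtures, built in code at test time.

# tiny design: 2 slots, promoters with known categories and short sequences
tiny_design <- function(seed = 7, prom_len = 60, unit_len = 120) {
  combilib:::with_seed(seed, {
    parts <- list(
      promoter_part("pS1", "strong", combilib:::random_dna(prom_len)),
      promoter_part("pS2", "strong", combilib:::random_dna(prom_len)),
      promoter_part("pM1", "medium", combilib:::random_dna(prom_len)),
      promoter_part("pW1", "weak", combilib:::random_dna(prom_len)))
    units <- list(gene_unit("gA", combilib:::random_dna(unit_len)),
                  gene_unit("gB", combilib:::random_dna(unit_len)))
    library_design(list(gA = c("pS1", "pS2", "pM1", "pW1"),
                        gB = c("pS1", "pS2", "pM1", "pW1")),
                   parts, units)
  })
}

# the default synthetic world, built once per test session
the_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- synthetic_world(42)
    w
  }
})

# expected verdict for each simulated truth kind
expected_verdict <- c(multigene = "multigene",
                      single_gene = "digested_single",
                      undigested_single = "undigested_single",
                      contaminant = "decoy")

# join truth and identifications; identification columns get an id_ prefix
join_truth <- function(truth, ids) {
  m <- match(truth$read_id, ids$read_name)
  stopifnot(!anyNA(m))
  idp <- ids[m, , drop = FALSE]
  names(idp) <- paste0("id_", names(idp))
  rownames(idp) <- NULL
  cbind(truth, idp)
}

# slot-assignment correctness for identified assembly reads
slots_correct <- function(joined, genes) {
  ok <- rep(TRUE, nrow(joined))
  for (g in genes) {
    tcol <- joined[[paste0("prom_", g)]]
    icol <- joined[[paste0("id_prom_", g)]]
    if (is.null(tcol) || is.null(icol)) next
    here <- !is.na(tcol)
    ok[here] <- ok[here] & !is.na(icol[here]) & icol[here] == tcol[here]
  }
  ok
}

# build an alignment record row for hand-crafted chains
rec <- function(ref_name, ref_start, ref_aln_len, ref_total_len,
                read_name, read_start, read_aln_len, read_total_len,
                score = ref_aln_len, read_strand = "+") {
  data.frame(score = score, ref_name = ref_name, ref_start = ref_start,
             ref_aln_len = ref_aln_len, ref_strand = "+",
             ref_total_len = ref_total_len, read_name = read_name,
             read_start = read_start, read_aln_len = read_aln_len,
             read_strand = read_strand, read_total_len = read_total_len,
             blocks = NA_character_, stringsAsFactors = FALSE)
}

as_tab <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("alignment_tab", "data.frame")
  out
}

# flip alignment records as if the read had been reverse-complemented:
# strand toggles, forward-strand start reflects
flip_records <- function(tab) {
  tab$read_start <- tab$read_total_len - (tab$read_start + tab$read_aln_len)
  tab$read_strand <- ifelse(tab$read_strand == "+", "-", "+")
  tab
}
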