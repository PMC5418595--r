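# Ground-truthed synthetic inputs: random assemblies, digestion-enriched
# fragments, error-bearing long reads. All randomness flows from explicit
# seeds through a local RNG scope; no global RNG state leaks.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Per-base sequencing error model
#'
#' Independent per-base substitution, insertion and deletion probabilities,
#' a crude but controllable stand-in for nanopore consensus (2D) read error.
#' Defaults (3\% / 2\% / 2\%) approximate 2D-read error; they are a modelling
#' choice, not an estimate from any particular run.
#'
#' @param substitution,insertion,deletion Per-base probabilities, each in
#'   `[0, 1)`, summing to less than 1.
#' @return An object of class `error_model`.
#' @export
error_model <- function(substitution = 0.03, insertion = 0.02,
                        deletion = 0.02) {
  rates <- c(substitution = substitution, insertion = insertion,
             deletion = deletion)
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 1)
    stop("error rates must each lie in [0,1) and sum to < 1")
  structure(as.list(rates), class = "error_model")
}

#' Restriction-digest size-selection windows
#'
#' Inclusive fragment-length windows, in bp, emulating gel isolation of
#' digest products: one window for the multigene assembly digest and one per
#' single-gene assembly. Defaults are the windows used for the benzylpenicillin
#' pathway library: multigene 5,616-6,117 bp; pcbC 2,062-2,229 bp;
#' pclA 2,549-2,716 bp; penDE 1,885-2,052 bp.
#'
#' @param windows Named list of length-2 numeric vectors `c(min_bp, max_bp)`,
#'   keyed `"multigene"` or by gene name.
#' @return An object of class `size_windows`.
#' @export
size_windows <- function(windows = list(
                           multigene = c(5616, 6117),
                           pcbC = c(2062, 2229),
                           pclA = c(2549, 2716),
                           penDE = c(1885, 2052))) {
  stopifnot(is.list(windows), !is.null(names(windows)))
  for (w in windows) {
    stopifnot(length(w) == 2L, is.numeric(w))
    if (w[1] > w[2] || any(w <= 0)) stop("each window needs 0 < min <= max")
  }
  structure(windows, class = "size_windows")
}

# Geometry making every synthetic fragment land inside the default windows:
# the three single-gene windows are each 167 bp wide and the multigene window
# is 501 = 3 x 167 bp wide, which is jointly consistent with (i) every
# promoter+unit cassette lying in a common 1,872-2,039 bp range and (ii) each
# digested single-gene fragment retaining a gene-specific vector remnant
# (190 / 677 / 13 bp) between the cassette and the distal restriction site.
.SYN_GEOM <- list(
  prom_len = round(seq(600, 759, length.out = 10)),
  unit_len = c(pcbC = 1273, pclA = 1280, penDE = 1272),
  scar_len = c(pcbC = 190, pclA = 677, penDE = 13),
  backbone_len = c(AmpRTerm_AmpR_AmpRProm = 1177,
                   His3Prom_His3Term_2Micron_KanRTerm_KanR_KanRProm = 2600,
                   ColE1 = 600, lambda = 3000)
)

#' Build the default synthetic library world
#'
#' Constructs a fully specified synthetic counterpart of the benzylpenicillin
#' pathway promoter library: three gene slots (pcbC, pclA, penDE), ten
#' candidate promoters per slot (4 strong, 2 medium, 2 weak, 2 inducible;
#' theoretical diversity 1,000), random surrogate sequences with lengths chosen
#' so that every digested fragment falls inside the default
#' [size_windows()], plus backbone/decoy regions: the single-assembly and
#' multigene-assembly backbone parts, ColE1, a random 3 kb "lambda" surrogate
#' and the short vector remnants ("scars") digested single-gene fragments
#' retain.
#'
#' @param seed Integer seed controlling all surrogate sequences.
#' @return An object of class `synthetic_world`: list with `design`
#'   ([library_design()]), `db` ([build_reference_db()] output), `scars`
#'   (named list of remnant sequences per gene) and `backbone_single`
#'   (sequence appended to undigested single-gene plasmids).
#' @export
synthetic_world <- function(seed = 1L) {
  g <- .SYN_GEOM
  with_seed(seed, {
    prom_names <- c("pTDH3", "pCCW12", "pPGK1", "pTEF1",     # strong
                    "pRPL18B", "pSAC6",                      # medium
                    "pRNR2", "pREV1",                        # weak
                    "pGAL1", "pGAL10")                       # inducible
    cats <- rep(c("strong", "medium", "weak", "inducible"), c(4, 2, 2, 2))
    strengths <- c(100, 90, 75, 60, 25, 20, 8, 5, NA, NA)
    parts <- lapply(seq_along(prom_names), function(i)
      promoter_part(prom_names[i], cats[i], random_dna(g$prom_len[i]),
                    strengths[i]))
    units <- lapply(names(g$unit_len), function(gn)
      gene_unit(gn, random_dna(g$unit_len[[gn]])))
    slots <- setNames(rep(list(prom_names), length(g$unit_len)),
                      names(g$unit_len))
    design <- library_design(slots, parts, units)

    scars <- lapply(g$scar_len, random_dna)
    backbone <- lapply(g$backbone_len, random_dna)
    # scars long enough to align (>= the default min alignment score) are
    # themselves database regions; the 13 bp penDE remnant stays unaligned
    decoys <- c(backbone,
                list(bbScar_pcbC = scars$pcbC, bbScar_pclA = scars$pclA))
    decoy_class <- c("full", "full", "full", "contaminant", "scar", "scar")
    db <- build_reference_db(design, unlist(decoys), decoy_class)
    structure(list(design = design, db = db, scars = scars,
                   backbone_single = paste0(backbone$AmpRTerm_AmpR_AmpRProm,
                                            backbone$ColE1)),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic library world\n")
  print(x$design)
  print(x$db)
  invisible(x)
}

ASSEMBLY_KINDS <- c("multigene", "single_gene", "undigested_single")

#' Simulate one assembly instance
#'
#' Draws a promoter independently for each relevant slot (uniformly, or from a
#' user-supplied biased distribution to emulate assembly bias) and concatenates
#' the corresponding sequences:
#' \describe{
#'   \item{multigene}{`promoter + unit` for every slot, in slot order.}
#'   \item{single_gene}{one `promoter + unit` cassette plus the gene's short
#'     vector remnant (the digested fragment as gel-purified).}
#'   \item{undigested_single}{the cassette plus remnant plus the complete
#'     single-assembly backbone (the product of incomplete digestion).}
#' }
#'
#' @param world A [synthetic_world()] (or a bare [library_design()], in which
#'   case remnants and backbone are empty and only `"multigene"` /
#'   `"single_gene"` kinds are available).
#' @param kind One of `"multigene"`, `"single_gene"`, `"undigested_single"`.
#' @param gene Gene for single kinds; default: drawn uniformly.
#' @param bias Optional named list: gene -> named probability vector over that
#'   slot's candidate promoters.
#' @param seed Optional integer seed.
#' @return An object of class `assembly_instance`: list with `kind`, `gene`
#'   (NA for multigene), `promoter_choice` (named character), `sequence`,
#'   `truth_id`.
#' @export
simulate_assembly <- function(world, kind = ASSEMBLY_KINDS, gene = NULL,
                              bias = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (inherits(world, "library_design"))
    world <- list(design = world, scars = list(), backbone_single = "")
  design <- world$design
  with_seed(seed, {
    draw_slot <- function(g) {
      cand <- design$slots[[g]]
      p <- bias[[g]]
      if (is.null(p)) return(sample(cand, 1L))
      stopifnot(all(names(p) %in% cand))
      sample(names(p), 1L, prob = p)
    }
    if (kind == "multigene") {
      genes <- names(design$slots)
      choice <- vapply(genes, draw_slot, "")
      seqs <- unlist(lapply(genes, function(g)
        c(design$parts[[choice[[g]]]]$sequence, design$units[[g]]$sequence)))
      sequence <- paste(seqs, collapse = "")
      gene <- NA_character_
    } else {
      if (is.null(gene)) gene <- sample(names(design$slots), 1L)
      if (!gene %in% names(design$slots)) stop("unknown gene slot: ", gene)
      choice <- setNames(draw_slot(gene), gene)
      scar <- world$scars[[gene]] %||% ""
      sequence <- paste0(design$parts[[choice[[gene]]]]$sequence,
                         design$units[[gene]]$sequence, scar)
      if (kind == "undigested_single")
        sequence <- paste0(sequence, world$backbone_single)
    }
    structure(list(kind = kind, gene = gene, promoter_choice = choice,
                   sequence = sequence,
                   truth_id = paste0(substr(kind, 1, 2), "_",
                                     paste(choice, collapse = "-"),
                                     if (!is.na(gene)) paste0("_", gene))),
              class = "assembly_instance")
  })
}

#' Size-select a digest fragment
#'
#' Emulates gel isolation of restriction-digest products: the fragment is
#' accepted iff its length lies inside the window for its kind/gene
#' (bounds inclusive). Rejection is a value, not an error.
#'
#' @param instance An [simulate_assembly()] result (or any object with
#'   `kind`, `gene`, `sequence`).
#' @param windows A [size_windows()].
#' @return The fragment sequence (character) if accepted, otherwise `NA`.
#' @export
digest_and_select <- function(instance, windows = size_windows()) {
  stopifnot(inherits(windows, "size_windows"))
  key <- if (instance$kind == "multigene") "multigene" else instance$gene
  w <- windows[[key]]
  if (is.null(w))
    stop("no size window defined for kind/gene '", key, "'")
  len <- nchar(instance$sequence)
  if (len >= w[1] && len <= w[2]) instance$sequence else NA_character_
}

# Apply per-base substitution / insertion / deletion errors to one sequence.
mutate_sequence <- function(sequence, model) {
  bases <- c("A", "C", "G", "T")
  x <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(x)
  u <- runif(n)
  del <- u < model$deletion
  sub <- !del & u < model$deletion + model$substitution
  if (any(sub)) {
    # substitute with a uniformly chosen *different* base
    shift <- sample.int(3L, sum(sub), replace = TRUE)
    x[sub] <- bases[((match(x[sub], bases) - 1L + shift) %% 4L) + 1L]
  }
  x[del] <- ""
  ins <- runif(n) < model$insertion
  if (any(ins)) {
    x[ins] <- paste0(x[ins], sample(bases, sum(ins), replace = TRUE))
  }
  paste(x, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Simulate long reads from fragments
#'
#' Each read derives from one fragment, full length, on a uniformly random
#' strand, with independent per-base errors applied according to `model`.
#' Output is deterministic given `seed`.
#'
#' @param fragments A list of [simulate_assembly()] instances, or a named
#'   character vector of fragment sequences.
#' @param model An [error_model()].
#' @param n_reads Number of reads; fragments are sampled uniformly with
#'   replacement unless `n_reads` equals the number of fragments, in which
#'   case each fragment yields exactly one read.
#' @param seed Integer seed.
#' @return A list with `reads` (named character vector) and `truth`
#'   (data.frame: read_id, truth_id, kind, gene, strand, one `prom_<gene>`
#'   column per design slot present in the fragments).
#' @export
simulate_reads <- function(fragments, model = error_model(), n_reads = NULL,
                           seed = 1L) {
  if (length(fragments) == 0L) stop("empty fragment list")
  stopifnot(inherits(model, "error_model"))
  if (is.character(fragments)) {
    nm <- names(fragments) %||% paste0("frag", seq_along(fragments))
    fragments <- lapply(seq_along(fragments), function(i)
      list(kind = "fragment", gene = NA_character_,
           promoter_choice = character(), sequence = fragments[[i]],
           truth_id = nm[i]))
  }
  if (is.null(n_reads)) n_reads <- length(fragments)
  with_seed(seed, {
    idx <- if (n_reads == length(fragments)) seq_len(n_reads)
           else sample.int(length(fragments), n_reads, replace = TRUE)
    strands <- ifelse(runif(n_reads) < 0.5, "+", "-")
    reads <- character(n_reads)
    rows <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      fr <- fragments[[idx[i]]]
      s <- mutate_sequence(fr$sequence, model)
      if (strands[i] == "-") s <- revcomp(s)
      reads[i] <- s
      prom <- as.list(fr$promoter_choice)
      names(prom) <- if (length(prom)) paste0("prom_", names(prom))
      rows[[i]] <- c(list(read_id = sprintf("read_%05d", i),
                          truth_id = fr$truth_id, kind = fr$kind,
                          gene = fr$gene, strand = strands[i]), prom)
    }
    all_cols <- unique(unlist(lapply(rows, names)))
    truth <- do.call(rbind, lapply(rows, function(r) {
      r[setdiff(all_cols, names(r))] <- NA_character_
      as.data.frame(r[all_cols], stringsAsFactors = FALSE)
    }))
    names(reads) <- truth$read_id
    list(reads = reads, truth = truth)
  })
}

#' Simulate a full sequencing run of a library construction
#'
#' Generates a pooled, digestion-enriched sequencing run: multigene assemblies,
#' digested and undigested single-gene assemblies (fresh random assembly per
#' read) and contaminant reads drawn from the contaminant/multigene-backbone
#' decoys. Default class proportions emulate an equimolar pool of the
#' multigene library and the three single-gene libraries (25\% each), with
#' 10\% of each single-gene library escaping digestion and 5\% of all reads
#' being contaminants.
#'
#' @param world A [synthetic_world()].
#' @param n_reads Total number of reads.
#' @param model An [error_model()].
#' @param proportions Named numeric: `multigene`, `single_gene`,
#'   `undigested_single`, `contaminant`; normalised internally.
#' @param bias Optional incorporation bias passed to [simulate_assembly()].
#' @param seed Integer seed.
#' @param size_select Apply [digest_and_select()] to digested fragments
#'   (default TRUE; with the default world geometry nothing is rejected).
#' @return As [simulate_reads()].
#' @export
simulate_run <- function(world, n_reads = 500, model = error_model(),
                         proportions = c(multigene = 0.2375,
                                         single_gene = 0.64125,
                                         undigested_single = 0.07125,
                                         contaminant = 0.05),
                         bias = NULL, seed = 1L, size_select = TRUE) {
  stopifnot(inherits(world, "synthetic_world"))
  p <- proportions[c("multigene", "single_gene", "undigested_single",
                     "contaminant")]
  stopifnot(!anyNA(p), all(p >= 0), sum(p) > 0)
  p <- p / sum(p)
  genes <- names(world$design$slots)
  contam <- world$db$meta$name[world$db$meta$role == "decoy" &
                                 world$db$meta$class %in% c("contaminant", "full")]
  contam <- setdiff(contam, c("bbScar_pcbC", "bbScar_pclA"))
  with_seed(seed, {
    kinds <- sample(names(p), n_reads, replace = TRUE, prob = p)
    fragments <- lapply(kinds, function(k) {
      if (k == "contaminant") {
        nm <- sample(contam, 1L)
        return(list(kind = "contaminant", gene = NA_character_,
                    promoter_choice = character(),
                    sequence = world$db$seq[[nm]], truth_id = nm))
      }
      inst <- simulate_assembly(world, k, bias = bias)
      if (size_select && k != "undigested_single") {
        frag <- digest_and_select(inst)
        if (is.na(frag))
          stop("internal: default-geometry fragment rejected by size window")
        inst$sequence <- frag
      }
      inst
    })
    simulate_reads(fragments, model, seed = NULL)
  })
}

#' Write reads as FASTA or FASTQ
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path; format chosen by `format`.
#' @param format `"fasta"` or `"fastq"` (FASTQ gets uniform dummy qualities).
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(reads)
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, filepath = path)
  } else {
    q <- vapply(Biostrings::width(x), function(w)
      paste(rep("I", w), collapse = ""), "")
    lines <- as.vector(rbind(paste0("@", names(reads)), as.character(x),
                             "+", q))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write a read truth table as TSV
#' @param truth Truth data.frame from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
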