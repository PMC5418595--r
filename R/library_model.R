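#' @useDynLib combilib, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pchisq rmultinom runif setNames lm coef p.adjust aggregate dhyper
#' @importFrom utils read.delim write.table head tail
"_PACKAGE"

PROMOTER_CATEGORIES <- c("strong", "medium", "weak", "inducible")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create a promoter part
#'
#' A promoter part is the unit whose incorporation frequency is under test:
#' a named DNA sequence belonging to one of four strength categories
#' (strong, medium, weak, inducible). Relative strength in arbitrary units is
#' optional metadata; no computation depends on it.
#'
#' @param name Unique part name (e.g. `"pTDH3"`).
#' @param category One of `"strong"`, `"medium"`, `"weak"`, `"inducible"`.
#'   The category set is closed; anything else is an error, not coerced.
#' @param sequence DNA string over `A`, `C`, `G`, `T` (case-insensitive).
#' @param strength Optional relative expression strength (arbitrary units).
#' @return An object of class `promoter_part`.
#' @export
promoter_part <- function(name, category, sequence, strength = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  category <- match.arg(category, PROMOTER_CATEGORIES)
  sequence <- .check_dna(sequence, paste0("promoter '", name, "'"))
  structure(
    list(name = name, category = category, sequence = sequence,
         strength = as.numeric(strength)),
    class = "promoter_part"
  )
}

#' Create a gene unit (combined CDS + terminator region)
#'
#' @param gene Gene identifier (e.g. `"pcbC"`).
#' @param sequence DNA string for the combined CDS+terminator region.
#' @return An object of class `gene_unit`.
#' @export
gene_unit <- function(gene, sequence) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  sequence <- .check_dna(sequence, paste0("gene unit '", gene, "'"))
  structure(list(gene = gene, sequence = sequence), class = "gene_unit")
}

.check_dna <- function(sequence, what) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence))
    stop(what, ": sequence must be non-empty", call. = FALSE)
  if (grepl("[^ACGT]", sequence))
    stop(what, ": sequence contains characters outside {A,C,G,T}", call. = FALSE)
  sequence
}

#' Define a combinatorial library design
#'
#' A design is an ordered list of gene slots, each with its set of candidate
#' promoters, backed by a promoter registry and a gene-unit registry. It is the
#' object every downstream stage (read classification, bias statistics,
#' synthetic data generation) is parameterised by.
#'
#' @param slots Named list: slot gene name -> character vector of candidate
#'   promoter names, in slot order.
#' @param parts List of [promoter_part()] objects.
#' @param units List of [gene_unit()] objects.
#' @return An object of class `library_design` with elements `slots`, `parts`
#'   (named list), `units` (named list).
#' @examples
#' p <- lapply(1:3, function(i)
#'   promoter_part(paste0("p", i), "strong", "ACGTACGT"))
#' u <- list(gene_unit("gfp", "ATGAAATAA"))
#' d <- library_design(list(gfp = c("p1", "p2", "p3")), p, u)
#' design_space_size(d)
#' @export
library_design <- function(slots, parts, units) {
  stopifnot(is.list(slots), length(slots) >= 1L, !is.null(names(slots)))
  stopifnot(all(vapply(parts, inherits, TRUE, "promoter_part")))
  stopifnot(all(vapply(units, inherits, TRUE, "gene_unit")))
  part_names <- vapply(parts, `[[`, "", "name")
  unit_names <- vapply(units, `[[`, "", "gene")
  if (anyDuplicated(part_names))
    stop("duplicate promoter part names: ",
         paste(unique(part_names[duplicated(part_names)]), collapse = ", "))
  if (anyDuplicated(unit_names))
    stop("duplicate gene unit names: ",
         paste(unique(unit_names[duplicated(unit_names)]), collapse = ", "))
  names(parts) <- part_names
  names(units) <- unit_names
  for (g in names(slots)) {
    cand <- slots[[g]]
    if (length(cand) < 1L)
      stop("slot '", g, "' has no candidate promoters")
    missing <- setdiff(cand, part_names)
    if (length(missing))
      stop("slot '", g, "' references unknown promoters: ",
           paste(missing, collapse = ", "))
    if (!g %in% unit_names)
      stop("slot gene '", g, "' has no gene unit in the registry")
  }
  structure(list(slots = slots, parts = parts, units = units),
            class = "library_design")
}

#' @export
print.library_design <- function(x, ...) {
  cat("Combinatorial library design\n")
  cat("  slots:", length(x$slots), "| promoters:", length(x$parts),
      "| design space:", design_space_size(x), "combinations\n")
  for (g in names(x$slots)) {
    cand <- x$slots[[g]]
    cats <- table(factor(vapply(x$parts[cand], `[[`, "", "category"),
                         levels = PROMOTER_CATEGORIES))
    cat(sprintf("  %-8s %2d candidates (%s)\n", g, length(cand),
                paste(names(cats)[cats > 0], cats[cats > 0],
                      sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' Size of the combinatorial design space
#'
#' The number of distinct promoter combinations the library can realise:
#' the product over slots of the number of candidate promoters.
#'
#' @param design A [library_design()].
#' @return A single number.
#' @export
design_space_size <- function(design) {
  stopifnot(inherits(design, "library_design"))
  if (length(design$slots) == 0L)
    stop("degenerate design: no slots")
  prod(vapply(design$slots, length, 1L))
}

#' Null (chance) promoter-category distribution at a slot
#'
#' Under random equimolar assembly, the probability that a slot receives a
#' promoter of a given category equals the fraction of that slot's candidates
#' that belong to the category. This is the "expected by chance" distribution
#' the incorporation-bias chi-squared test compares against.
#'
#' @param design A [library_design()].
#' @param gene Slot gene name.
#' @return Named numeric vector of probabilities over the four categories
#'   (zero-mass categories included); sums to 1.
#' @export
null_category_distribution <- function(design, gene) {
  stopifnot(inherits(design, "library_design"))
  if (!gene %in% names(design$slots))
    stop("unknown gene slot: ", gene)
  cand <- design$slots[[gene]]
  cats <- vapply(design$parts[cand], `[[`, "", "category")
  tab <- table(factor(cats, levels = PROMOTER_CATEGORIES))
  setNames(as.vector(tab) / length(cand), PROMOTER_CATEGORIES)
}

#' Slot category lookup helper
#' @param design A [library_design()].
#' @param promoter Promoter part name(s).
#' @return Character vector of categories.
#' @export
promoter_category <- function(design, promoter) {
  stopifnot(inherits(design, "library_design"))
  missing <- setdiff(promoter, names(design$parts))
  if (length(missing))
    stop("unknown promoter(s): ", paste(missing, collapse = ", "))
  vapply(design$parts[promoter], `[[`, "", "category")
}

#' Build the alignment reference database
#'
#' The database reads are aligned against: every candidate promoter, every
#' combined CDS+terminator gene unit, plus decoy regions (vector backbone
#' parts, a phage genome) included solely so contaminant and backbone-bearing
#' reads can be recognised. Decoys carry a class: `"full"` for complete
#' backbone regions whose presence marks an undigested plasmid, `"scar"` for
#' short vector remnants that digested fragments may legitimately retain, and
#' `"contaminant"` for foreign DNA (e.g. lambda phage).
#'
#' @param design A [library_design()].
#' @param decoys Named character vector of decoy DNA sequences (may be empty).
#' @param decoy_class Character vector parallel to `decoys`, each one of
#'   `"full"`, `"scar"`, `"contaminant"`. Defaults to `"contaminant"`.
#' @return An object of class `reference_db`: list with `seq` (named character
#'   vector of sequences) and `meta` (data.frame: name, role, class, length).
#' @export
build_reference_db <- function(design, decoys = character(),
                               decoy_class = NULL) {
  stopifnot(inherits(design, "library_design"))
  pn <- names(design$parts)
  un <- names(design$units)
  dn <- names(decoys)
  if (length(decoys)) {
    stopifnot(!is.null(dn), all(nzchar(dn)))
    decoys <- vapply(seq_along(decoys),
                     function(i) .check_dna(decoys[[i]], paste0("decoy '", dn[i], "'")),
                     "")
    names(decoys) <- dn
  }
  all_names <- c(pn, un, dn)
  if (anyDuplicated(all_names))
    stop("reference region name collision: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  if (is.null(decoy_class)) decoy_class <- rep("contaminant", length(decoys))
  stopifnot(length(decoy_class) == length(decoys),
            all(decoy_class %in% c("full", "scar", "contaminant")))
  seqs <- c(vapply(design$parts, `[[`, "", "sequence"),
            vapply(design$units, `[[`, "", "sequence"),
            as.character(decoys))
  names(seqs) <- all_names
  meta <- data.frame(
    name = all_names,
    role = c(rep("promoter", length(pn)), rep("gene_unit", length(un)),
             rep("decoy", length(dn))),
    class = c(rep(NA_character_, length(pn) + length(un)), decoy_class),
    length = nchar(seqs),
    stringsAsFactors = FALSE
  )
  structure(list(seq = seqs, meta = meta), class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("Reference database:", nrow(x$meta), "regions (",
      sum(x$meta$role == "promoter"), "promoters,",
      sum(x$meta$role == "gene_unit"), "gene units,",
      sum(x$meta$role == "decoy"), "decoys ),",
      sum(x$meta$length), "bp total\n")
  invisible(x)
}

#' Region role lookup
#' @param db A `reference_db`.
#' @param name Region name(s).
#' @return Character vector of roles.
#' @export
region_role <- function(db, name) {
  stopifnot(inherits(db, "reference_db"))
  i <- match(name, db$meta$name)
  if (anyNA(i)) stop("unknown region(s): ",
                     paste(name[is.na(i)], collapse = ", "))
  db$meta$role[i]
}

#' Write a reference database as multi-record FASTA
#' @param db A `reference_db`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(db, path) {
  stopifnot(inherits(db, "reference_db"))
  x <- Biostrings::DNAStringSet(db$seq)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a design from a FASTA file plus a manifest
#'
#' The manifest is a TSV/CSV with columns `name`, `role`
#' (promoter/gene_unit/decoy), `gene` (slot gene for promoters: the slot(s) the
#' promoter is a candidate for, comma-separated; the gene itself for units),
#' `category` (promoters only) and optional `strength` and `class` (decoys).
#' Sequences are looked up in the FASTA by `name`.
#'
#' @param fasta Path to a FASTA of all part sequences.
#' @param manifest Path to the manifest table (TSV by default).
#' @param sep Field separator for the manifest.
#' @return A list with `design` ([library_design()]) and `db`
#'   ([build_reference_db()] output including any decoys).
#' @export
read_design <- function(fasta, manifest, sep = "\t") {
  seqs <- Biostrings::readDNAStringSet(fasta)
  nm <- sub("\\s.*$", "", names(seqs))
  seqv <- setNames(as.character(seqs), nm)
  man <- read.delim(manifest, sep = sep, stringsAsFactors = FALSE)
  need <- c("name", "role", "gene")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(man$name, nm)
  if (length(missing))
    stop("manifest names absent from FASTA: ", paste(missing, collapse = ", "))
  pm <- man[man$role == "promoter", , drop = FALSE]
  um <- man[man$role == "gene_unit", , drop = FALSE]
  dm <- man[man$role == "decoy", , drop = FALSE]
  parts <- lapply(seq_len(nrow(pm)), function(i)
    promoter_part(pm$name[i], pm$category[i], seqv[[pm$name[i]]],
                  if ("strength" %in% names(pm)) pm$strength[i] else NA_real_))
  units <- lapply(seq_len(nrow(um)), function(i)
    gene_unit(um$gene[i], seqv[[um$name[i]]]))
  genes <- um$gene
  slots <- lapply(genes, function(g) {
    cand <- pm$name[vapply(strsplit(pm$gene, ","),
                           function(s) g %in% trimws(s), TRUE)]
    cand
  })
  names(slots) <- genes
  design <- library_design(slots, parts, units)
  decoys <- setNames(unname(seqv[dm$name]), dm$name)
  dclass <- if ("class" %in% names(dm) && nrow(dm)) dm$class
            else rep("contaminant", nrow(dm))
  db <- build_reference_db(design, decoys, dclass)
  list(design = design, db = db)
}
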