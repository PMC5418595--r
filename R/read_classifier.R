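# Read identification: chain per-read alignments, match the chain against
# construct templates, enforce the length and end-anchoring rules, record the
# promoter at each gene slot.

#' Chain alignment records per read
#'
#' Groups records by read and sorts them by forward-strand read coordinate.
#' Overlapping alignments to the same region are collapsed to the
#' highest-scoring one. Chains whose segments hit no promoter or gene-unit
#' region at all (pure backbone / contaminant reads) are flagged as decoy and
#' excluded from identification downstream.
#'
#' @param records An `alignment_tab` data.frame ([parse_alignment_table()],
#'   [naive_align()], [align_reads()]).
#' @param db A `reference_db`; provides each segment's role and decoy class.
#' @return A list of `read_chain` objects: each has `read_name`,
#'   `read_total_len`, `segments` (data.frame with added `role`/`class`
#'   columns, sorted by `read_start`), `decoy` (logical).
#' @export
chain_reads <- function(records, db) {
  validate_alignment_tab(records)
  stopifnot(inherits(db, "reference_db"))
  i <- match(records$ref_name, db$meta$name)
  if (anyNA(i))
    stop("alignment references unknown region(s): ",
         paste(unique(records$ref_name[is.na(i)]), collapse = ", "))
  records$role <- db$meta$role[i]
  records$class <- db$meta$class[i]
  chains <- lapply(split(records, records$read_name), function(seg) {
    seg <- seg[order(seg$read_start, -seg$score), , drop = FALSE]
    seg <- collapse_overlaps(seg)
    seg <- seg[order(seg$read_start, -seg$score), , drop = FALSE]
    rownames(seg) <- NULL
    structure(list(read_name = seg$read_name[1],
                   read_total_len = seg$read_total_len[1],
                   segments = seg,
                   decoy = !any(seg$role %in% c("promoter", "gene_unit"))),
              class = "read_chain")
  })
  unname(chains)
}

# keep the best-scoring of any set of same-region alignments that overlap on
# the read (greedy by score)
collapse_overlaps <- function(seg) {
  if (nrow(seg) < 2) return(seg)
  ord <- order(-seg$score)
  keep <- logical(nrow(seg))
  for (k in ord) {
    s <- seg$read_start[k]; e <- s + seg$read_aln_len[k]
    clash <- keep & seg$ref_name == seg$ref_name[k] &
      seg$read_start < e & (seg$read_start + seg$read_aln_len) > s
    if (!any(clash)) keep[k] <- TRUE
  }
  seg[keep, , drop = FALSE]
}

#' @export
print.read_chain <- function(x, ...) {
  cat(sprintf("read_chain %s (%d bp%s): %s\n", x$read_name, x$read_total_len,
              if (x$decoy) ", decoy" else "",
              paste(x$segments$ref_name, collapse = " > ")))
  invisible(x)
}

# segments reordered into template orientation: majority aligned-length strand
# decides; for '-' the physical order is reversed.
canonical_orientation <- function(chain) {
  seg <- chain$segments
  minus <- sum(seg$read_aln_len[seg$read_strand == "-"])
  plus <- sum(seg$read_aln_len[seg$read_strand == "+"])
  if (minus > plus) "-" else "+"
}

canonical_segments <- function(chain, orientation) {
  seg <- chain$segments
  if (orientation == "-") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
  seg
}

# head/tail slack between the read's extremity and the first/last region's
# extremity, in the template (canonical) frame
anchor_offsets <- function(seg, orientation, read_len) {
  first <- seg[1, ]; last <- seg[nrow(seg), ]
  if (orientation == "+") {
    head_read <- first$read_start
    tail_read <- read_len - (last$read_start + last$read_aln_len)
  } else {
    head_read <- read_len - (first$read_start + first$read_aln_len)
    tail_read <- last$read_start
  }
  head_ref <- first$ref_start
  tail_ref <- last$ref_total_len - (last$ref_start + last$ref_aln_len)
  c(head = abs(head_read - head_ref), tail = abs(tail_read - tail_ref))
}

# Match a canonically ordered role sequence against the construct templates.
# Returns list(verdict, gene, slots) or list(reason = <tag>).
match_template <- function(seg, design) {
  roles <- seg$role
  names_ <- seg$ref_name
  if (any(roles == "decoy" & seg$class == "contaminant"))
    return(list(reason = "contaminant"))
  core_idx <- which(roles %in% c("promoter", "gene_unit"))
  # backbone segments may only flank the cassette(s)
  if (length(core_idx) &&
      !identical(core_idx, seq(min(core_idx), max(core_idx))))
    return(list(reason = "template"))
  pre <- if (min(core_idx) > 1) seg[seq_len(min(core_idx) - 1), ] else NULL
  post <- if (max(core_idx) < nrow(seg))
    seg[seq(max(core_idx) + 1, nrow(seg)), ] else NULL
  flank_class <- c(pre$class, post$class)
  core_roles <- roles[core_idx]
  core_names <- names_[core_idx]
  k <- length(core_roles)
  if (k %% 2L != 0L ||
      !all(core_roles == rep(c("promoter", "gene_unit"), k / 2))) {
    # two promoters immediately upstream of a unit is the classic ambiguity
    amb <- any(core_roles[-k] == "promoter" &
                 core_roles[-1] == "promoter") &&
      any(core_roles == "gene_unit")
    return(list(reason = if (amb) "ambiguous" else "template"))
  }
  genes <- core_names[seq(2, k, by = 2)]
  proms <- core_names[seq(1, k, by = 2)]
  if (!all(genes %in% names(design$slots)))
    stop("chain references gene unit(s) absent from the design: ",
         paste(setdiff(genes, names(design$slots)), collapse = ", "))
  for (s in seq_along(genes))
    if (!proms[s] %in% design$slots[[genes[s]]])
      return(list(reason = "slot_assignment"))
  if (k / 2 == length(design$slots)) {
    if (!identical(genes, names(design$slots)))
      return(list(reason = "template"))
    if (length(flank_class))          # digested multigene carries no backbone
      return(list(reason = "template"))
    return(list(verdict = "multigene", gene = NA_character_,
                slots = setNames(proms, genes)))
  }
  if (k / 2 == 1L) {
    verdict <- if (any(flank_class == "full")) "undigested_single"
               else "digested_single"
    return(list(verdict = verdict, gene = genes,
                slots = setNames(proms, genes)))
  }
  list(reason = "template")
}

#' Identify the construct a read chain represents
#'
#' Applies the identification rules in order: (i) the chain's ordered region
#' names must match a construct template — a full multigene assembly
#' (promoter+unit for every slot, in slot order), a digested single-gene
#' assembly (one promoter+unit cassette, possibly flanked by short vector
#' remnants), or an undigested single-gene assembly (cassette plus complete
#' backbone regions); chains are canonicalised by overall strand first, and
#' the reverse order is also tried. (ii) The read length must lie within
#' `length_tol` (default 15\%, boundary inclusive) of the summed full lengths
#' of the regions it aligned to. (iii) Digested single-gene reads must
#' additionally start and finish within `end_tol` (default 50 bp) of the first
#' and final regions' extremities — this guards against a multigene read with
#' a partial chain being mistaken for a single-gene read. On success the
#' promoter immediately upstream of each gene unit is recorded per slot.
#'
#' @param chain A `read_chain` (non-decoy) from [chain_reads()].
#' @param design A [library_design()].
#' @param length_tol Relative length tolerance (inclusive).
#' @param end_tol End-anchoring tolerance in bp (inclusive).
#' @return A list of class `read_identification`: `read_name`, `verdict`
#'   (`multigene`, `digested_single`, `undigested_single`, `unidentified`),
#'   `gene`, `slot_promoters` (named character), `length_ratio`, `reasons`.
#' @export
identify_read <- function(chain, design, length_tol = 0.15, end_tol = 50) {
  stopifnot(inherits(chain, "read_chain"), inherits(design, "library_design"))
  if (isTRUE(chain$decoy))
    stop("identify_read() expects a non-decoy chain; filter with chain_reads()")
  read_len <- chain$read_total_len
  region_sum <- sum(chain$segments$ref_total_len)
  ratio <- read_len / region_sum
  fail <- function(reasons) structure(
    list(read_name = chain$read_name, verdict = "unidentified",
         gene = NA_character_, slot_promoters = NULL,
         length_ratio = ratio, reasons = reasons),
    class = "read_identification")

  orientation <- canonical_orientation(chain)
  hit <- NULL
  for (ori in unique(c(orientation, setdiff(c("+", "-"), orientation)))) {
    seg <- canonical_segments(chain, ori)
    m <- match_template(seg, design)
    if (!is.null(m$verdict)) { hit <- m; hit$seg <- seg; hit$ori <- ori; break }
    if (is.null(hit)) hit <- m              # keep first failure reason
  }
  if (is.null(hit$verdict)) return(fail(hit$reason))
  if (abs(ratio - 1) > length_tol + 1e-12) return(fail("length"))
  if (hit$verdict == "digested_single") {
    off <- anchor_offsets(hit$seg, hit$ori, read_len)
    if (any(off > end_tol)) return(fail("end_anchor"))
  }
  structure(list(read_name = chain$read_name, verdict = hit$verdict,
                 gene = hit$gene, slot_promoters = hit$slots,
                 length_ratio = ratio, reasons = character()),
            class = "read_identification")
}

#' Identify all chains of a run
#'
#' Runs [identify_read()] over every non-decoy chain and returns one row per
#' chained read (decoy chains get verdict `"decoy"`), so that the verdicts
#' partition the chained reads exactly.
#'
#' @param chains List of `read_chain` from [chain_reads()].
#' @param design A [library_design()].
#' @param length_tol,end_tol See [identify_read()].
#' @return A data.frame of class `identification_tab`: `read_name`, `verdict`,
#'   `gene`, `length_ratio`, `reason`, plus one `prom_<gene>` column per slot.
#' @export
identify_reads <- function(chains, design, length_tol = 0.15, end_tol = 50) {
  genes <- names(design$slots)
  if (!length(chains)) {
    out <- data.frame(read_name = character(), verdict = character(),
                      gene = character(), length_ratio = numeric(),
                      reason = character(), stringsAsFactors = FALSE)
    for (g in genes) out[[paste0("prom_", g)]] <- character()
    class(out) <- c("identification_tab", "data.frame")
    return(out)
  }
  rows <- lapply(chains, function(ch) {
    if (isTRUE(ch$decoy)) {
      id <- list(read_name = ch$read_name, verdict = "decoy",
                 gene = NA_character_, slot_promoters = NULL,
                 length_ratio = NA_real_, reasons = character())
    } else {
      id <- identify_read(ch, design, length_tol, end_tol)
    }
    prom <- setNames(rep(NA_character_, length(genes)),
                     paste0("prom_", genes))
    if (!is.null(id$slot_promoters))
      prom[paste0("prom_", names(id$slot_promoters))] <- id$slot_promoters
    c(list(read_name = id$read_name, verdict = id$verdict, gene = id$gene,
           length_ratio = id$length_ratio,
           reason = paste(id$reasons, collapse = ";")),
      as.list(prom))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("identification_tab", "data.frame")
  out
}

#' Tabulate promoters per gene slot
#'
#' Counts, per slot and candidate promoter, how often each promoter was
#' recorded among identified reads of a construction stage: multigene reads
#' contribute one observation per slot, single-gene reads one observation at
#' their slot. Unidentified and decoy reads contribute nothing. Category
#' counts derive from the part registry.
#'
#' @param identifications An `identification_tab` from [identify_reads()].
#' @param design A [library_design()].
#' @param stage Stage label (e.g. `"single_gene"`, `"multigene"`).
#' @param include Verdicts to count (defaults to all identified classes;
#'   drop `"undigested_single"` to exclude incomplete digests).
#' @return A data.frame of class `promoter_counts`: `stage`, `gene`,
#'   `promoter`, `category`, `count` over the full candidate grid.
#' @export
tabulate_promoters <- function(identifications, design, stage = "library",
                               include = c("multigene", "digested_single",
                                           "undigested_single")) {
  stopifnot(inherits(design, "library_design"))
  genes <- names(design$slots)
  grid <- do.call(rbind, lapply(genes, function(g)
    data.frame(stage = stage, gene = g, promoter = design$slots[[g]],
               category = promoter_category(design, design$slots[[g]]),
               stringsAsFactors = FALSE)))
  grid$count <- 0L
  idf <- identifications[identifications$verdict %in% include, , drop = FALSE]
  for (g in genes) {
    col <- paste0("prom_", g)
    obs <- idf[[col]]
    obs <- obs[!is.na(obs)]
    unknown <- setdiff(obs, design$slots[[g]])
    if (length(unknown))
      stop("recorded promoter(s) not candidates at slot '", g, "': ",
           paste(unknown, collapse = ", "))
    if (length(obs)) {
      tt <- table(factor(obs, levels = design$slots[[g]]))
      i <- which(grid$gene == g)
      grid$count[i] <- grid$count[i] + as.integer(tt[grid$promoter[i]])
    }
  }
  class(grid) <- c("promoter_counts", "data.frame")
  grid
}

#' Category-level counts from a promoter count table
#' @param counts A `promoter_counts` data.frame.
#' @return data.frame `stage`, `gene`, `category`, `count`.
#' @export
category_counts <- function(counts) {
  stopifnot(inherits(counts, "promoter_counts"))
  agg <- aggregate(count ~ stage + gene + category, data = counts, FUN = sum)
  agg[order(agg$stage, agg$gene, match(agg$category, PROMOTER_CATEGORIES)), ]
}

#' Classify reads end-to-end
#'
#' Pipeline convenience: align (unless an alignment table is supplied), chain,
#' identify, tabulate.
#'
#' @param reads Named character vector of reads (ignored when `tab` given).
#' @param design A [library_design()].
#' @param db A `reference_db`.
#' @param tab Optional pre-computed `alignment_tab` (e.g. parsed LAST output).
#' @param length_tol,end_tol See [identify_read()].
#' @param min_score Minimum alignment score when aligning internally.
#' @param stage Stage label for the count table.
#' @return List with `alignments`, `chains`, `identifications`, `counts`.
#' @export
classify_reads <- function(reads = NULL, design, db, tab = NULL,
                           length_tol = 0.15, end_tol = 50, min_score = 50,
                           stage = "library") {
  if (is.null(tab)) {
    stopifnot(!is.null(reads))
    tab <- align_reads(reads, db, min_score = min_score)
  }
  if (!nrow(tab)) {
    ids <- identify_reads(list(), design)
    return(list(alignments = tab, chains = list(), identifications = ids,
                counts = tabulate_promoters(ids, design, stage)))
  }
  chains <- chain_reads(tab, db)
  ids <- identify_reads(chains, design, length_tol, end_tol)
  counts <- tabulate_promoters(ids, design, stage)
  list(alignments = tab, chains = chains, identifications = ids,
       counts = counts)
}
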