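# a synthetic db for hand-crafted chain tests: promoter 500 bp, unit 1500 bp,
# so a digested single-gene template sums to 2000 bp
chain_db <- function() {
  parts <- list(promoter_part("pX", "strong", strrep("A", 500)),
                promoter_part("pY", "weak", strrep("C", 500)))
  units <- list(gene_unit("gA", strrep("G", 1500)),
                gene_unit("gB", strrep("T", 1500)))
  d <- library_design(list(gA = c("pX", "pY"), gB = c("pX", "pY")),
                      parts, units)
  db <- build_reference_db(
    d, c(lambda = strrep("AC", 1500), bbFull = strrep("AG", 600),
         bbScar = strrep("GT", 100)),
    decoy_class = c("contaminant", "full", "scar"))
  list(design = d, db = db)
}

test_that("chains sort by read coordinate and collapse same-region overlaps", {
  cd <- chain_db()
  tab <- as_tab(
    rec("pX", 0, 400, 500, "A", 4000, 400, 6000),
    rec("gA", 0, 1400, 1500, "A", 10, 1400, 6000),
    rec("gB", 0, 1400, 1500, "A", 2000, 1400, 6000))
  ch <- chain_reads(tab, cd$db)
  expect_length(ch, 1)
  expect_equal(ch[[1]]$segments$read_start, c(10, 2000, 4000))

  # overlapping same-region records: highest score wins
  tab2 <- as_tab(
    rec("gA", 0, 1000, 1500, "B", 100, 1000, 3000, score = 90),
    rec("gA", 200, 1100, 1500, "B", 300, 1100, 3000, score = 120))
  ch2 <- chain_reads(tab2, cd$db)
  expect_equal(nrow(ch2[[1]]$segments), 1)
  expect_equal(ch2[[1]]$segments$score, 120)

  # non-overlapping repeats of the same region are both kept
  tab3 <- as_tab(
    rec("pX", 0, 500, 500, "C", 0, 500, 2500),
    rec("pX", 0, 500, 500, "C", 2000, 500, 2500))
  expect_equal(nrow(chain_reads(tab3, cd$db)[[1]]$segments), 2)

  expect_error(chain_reads(as_tab(rec("mystery", 0, 10, 20, "D", 0, 10, 20)),
                           cd$db), "unknown region")
})

test_that("pure-decoy chains are flagged and excluded", {
  cd <- chain_db()
  tab <- as_tab(rec("lambda", 0, 2800, 3000, "L", 50, 2800, 3000),
                rec("pX", 50, 450, 500, "M", 0, 450, 2000),
                rec("gA", 0, 1500, 1500, "M", 450, 1500, 2000))
  ch <- chain_reads(tab, cd$db)
  decoy <- vapply(ch, `[[`, TRUE, "decoy")
  expect_identical(decoy[order(vapply(ch, `[[`, "", "read_name"))],
                   c(TRUE, FALSE))
  expect_error(identify_read(ch[[which(decoy)]], cd$design), "non-decoy")
  ids <- identify_reads(ch, cd$design)
  expect_setequal(ids$verdict, c("decoy", "digested_single"))
})

test_that("multigene identification satisfies the worked example", {
  cd <- chain_db()
  # [pX gA pY gB] over a 4000 bp template, read 4070 bp (ratio 1.0175)
  tab <- as_tab(
    rec("pX", 0, 500, 500, "R", 0, 500, 4070),
    rec("gA", 0, 1500, 1500, "R", 500, 1500, 4070),
    rec("pY", 0, 500, 500, "R", 2030, 500, 4070),
    rec("gB", 0, 1500, 1500, "R", 2550, 1500, 4070))
  id <- identify_read(chain_reads(tab, cd$db)[[1]], cd$design)
  expect_equal(id$verdict, "multigene")
  expect_equal(id$slot_promoters, c(gA = "pX", gB = "pY"))
  expect_equal(id$length_ratio, 4070 / 4000)
})

test_that("the 15% length rule is inclusive at the boundary", {
  cd <- chain_db()
  # extra read length sits in an interior (unconstrained) gap so only the
  # global length rule is exercised; template sums to 2000
  mk <- function(read_len) as_tab(
    rec("pX", 0, 500, 500, "R", 0, 500, read_len),
    rec("gA", 0, 1500, 1500, "R", read_len - 1500, 1500, read_len))
  # read 2300 is exactly +15% -> accepted
  id_at <- identify_read(chain_reads(mk(2300), cd$db)[[1]], cd$design)
  expect_equal(id_at$verdict, "digested_single")
  expect_equal(id_at$length_ratio, 1.15)
  id_over <- identify_read(chain_reads(mk(2301), cd$db)[[1]], cd$design)
  expect_equal(id_over$verdict, "unidentified")
  expect_equal(id_over$reasons, "length")

  # lower side: a partially covered unit; 1700/2000 = -15% exactly
  mk_lo <- function(read_len) as_tab(
    rec("pX", 0, 500, 500, "R", 0, 500, read_len),
    rec("gA", 0, read_len - 500, 1500, "R", 500, read_len - 500, read_len))
  expect_equal(identify_read(chain_reads(mk_lo(1700), cd$db)[[1]],
                             cd$design)$verdict, "unidentified")  # end anchor
  expect_equal(identify_read(chain_reads(mk_lo(1700), cd$db)[[1]], cd$design,
                             end_tol = 1e6)$verdict, "digested_single")
  id_len <- identify_read(chain_reads(mk_lo(1699), cd$db)[[1]], cd$design,
                          end_tol = 1e6)
  expect_equal(id_len$verdict, "unidentified")
  expect_equal(id_len$reasons, "length")

  # tightening the tolerance never identifies more reads (monotonicity)
  for (read_len in c(2000, 2120, 2290, 2300)) {
    v_tight <- identify_read(chain_reads(mk(read_len), cd$db)[[1]],
                             cd$design, length_tol = 0.05)$verdict
    v_loose <- identify_read(chain_reads(mk(read_len), cd$db)[[1]],
                             cd$design, length_tol = 0.15)$verdict
    expect_true(!(v_tight != "unidentified" & v_loose == "unidentified"))
  }
})

test_that("the 50 bp end anchor applies to digested singles only", {
  cd <- chain_db()
  # read starts 60 bp before the first region: digested single rejected
  mk <- function(lead) as_tab(
    rec("pX", 0, 500, 500, "R", lead, 500, 2000 + lead),
    rec("gA", 0, 1500, 1500, "R", lead + 500, 1500, 2000 + lead))
  id60 <- identify_read(chain_reads(mk(60), cd$db)[[1]], cd$design)
  expect_equal(id60$verdict, "unidentified")
  expect_equal(id60$reasons, "end_anchor")
  id50 <- identify_read(chain_reads(mk(50), cd$db)[[1]], cd$design)
  expect_equal(id50$verdict, "digested_single")   # inclusive at 50

  # trailing slack: read ends 70 bp after the final region
  tail_tab <- as_tab(
    rec("pX", 0, 500, 500, "R", 0, 500, 2070),
    rec("gA", 0, 1500, 1500, "R", 500, 1500, 2070))
  idt <- identify_read(chain_reads(tail_tab, cd$db)[[1]], cd$design)
  expect_equal(idt$reasons, "end_anchor")

  # a multigene chain with the same 60 bp lead is still accepted
  mg <- as_tab(
    rec("pX", 0, 500, 500, "R", 60, 500, 4060),
    rec("gA", 0, 1500, 1500, "R", 560, 1500, 4060),
    rec("pY", 0, 500, 500, "R", 2060, 500, 4060),
    rec("gB", 0, 1500, 1500, "R", 2560, 1500, 4060))
  expect_equal(identify_read(chain_reads(mg, cd$db)[[1]], cd$design)$verdict,
               "multigene")
})

test_that("single-gene verdicts split on backbone class and flag ambiguity", {
  cd <- chain_db()
  # cassette + scar remnant -> digested single
  dig <- as_tab(
    rec("pX", 0, 500, 500, "R", 0, 500, 2200),
    rec("gA", 0, 1500, 1500, "R", 500, 1500, 2200),
    rec("bbScar", 0, 200, 200, "R", 2000, 200, 2200))
  expect_equal(identify_read(chain_reads(dig, cd$db)[[1]], cd$design)$verdict,
               "digested_single")
  # cassette + full backbone -> undigested single
  und <- as_tab(
    rec("pX", 0, 500, 500, "R", 0, 500, 3200),
    rec("gA", 0, 1500, 1500, "R", 500, 1500, 3200),
    rec("bbFull", 0, 1200, 1200, "R", 2000, 1200, 3200))
  expect_equal(identify_read(chain_reads(und, cd$db)[[1]], cd$design)$verdict,
               "undigested_single")
  # contaminant segment inside an otherwise fine chain
  mix <- as_tab(
    rec("pX", 0, 500, 500, "R", 0, 500, 5000),
    rec("gA", 0, 1500, 1500, "R", 500, 1500, 5000),
    rec("lambda", 0, 3000, 3000, "R", 2000, 3000, 5000))
  idm <- identify_read(chain_reads(mix, cd$db)[[1]], cd$design)
  expect_equal(idm$verdict, "unidentified")
  expect_equal(idm$reasons, "contaminant")
  # two promoters immediately upstream of a unit -> ambiguous
  amb <- as_tab(
    rec("pX", 0, 500, 500, "R", 0, 500, 2500),
    rec("pY", 0, 500, 500, "R", 500, 500, 2500),
    rec("gA", 0, 1500, 1500, "R", 1000, 1500, 2500))
  ida <- identify_read(chain_reads(amb, cd$db)[[1]], cd$design)
  expect_equal(ida$verdict, "unidentified")
  expect_equal(ida$reasons, "ambiguous")
})

test_that("identification is invariant under read reverse-complementation", {
  w <- the_world()
  run <- simulate_run(w, n_reads = 12, seed = 61)
  tab <- align_reads(run$reads, w$db)
  ids_fwd <- identify_reads(chain_reads(tab, w$db), w$design)
  ids_rev <- identify_reads(chain_reads(flip_records(tab), w$db), w$design)
  ord <- order(ids_fwd$read_name)
  ord2 <- order(ids_rev$read_name)
  expect_identical(ids_fwd$verdict[ord], ids_rev$verdict[ord2])
  for (g in names(w$design$slots))
    expect_identical(ids_fwd[[paste0("prom_", g)]][ord],
                     ids_rev[[paste0("prom_", g)]][ord2])
})

test_that("verdicts partition the chained reads", {
  w <- the_world()
  run <- simulate_run(w, n_reads = 40, seed = 71)
  res <- classify_reads(run$reads, w$design, w$db)
  ids <- res$identifications
  expect_equal(nrow(ids), length(res$chains))
  expect_equal(anyDuplicated(ids$read_name), 0)
  n_decoy <- sum(vapply(res$chains, `[[`, TRUE, "decoy"))
  expect_equal(sum(ids$verdict != "decoy"), length(res$chains) - n_decoy)
  expect_true(all(ids$verdict %in% c("multigene", "digested_single",
                                     "undigested_single", "unidentified",
                                     "decoy")))
})

test_that("tabulation counts slots, conserves totals and handles empties", {
  cd <- chain_db()
  mk_id <- function(read, verdict, pA = NA, pB = NA, gene = NA)
    data.frame(read_name = read, verdict = verdict, gene = gene,
               length_ratio = 1, reason = "", prom_gA = pA, prom_gB = pB,
               stringsAsFactors = FALSE)
  ids <- rbind(mk_id("r1", "multigene", "pX", "pY"),
               mk_id("r2", "multigene", "pX", "pX"),
               mk_id("r3", "digested_single", pB = "pY", gene = "gB"),
               mk_id("r4", "unidentified"))
  class(ids) <- c("identification_tab", "data.frame")
  tab <- tabulate_promoters(ids, cd$design, stage = "s1")
  expect_equal(tab$count[tab$gene == "gA" & tab$promoter == "pX"], 2)
  expect_equal(sum(tab$count), 2 * 2 + 1)   # 2 multigene slots x 2 + 1 single
  cc <- category_counts(tab)
  expect_equal(sum(cc$count), sum(tab$count))
  expect_equal(cc$count[cc$gene == "gB" & cc$category == "weak"], 2)

  empty <- tabulate_promoters(ids[ids$verdict == "unidentified", ],
                              cd$design, stage = "s1")
  expect_true(all(empty$count == 0))

  bad <- mk_id("r9", "multigene", "pZ", "pY")
  class(bad) <- c("identification_tab", "data.frame")
  expect_error(tabulate_promoters(bad, cd$design), "not candidates")

  # undigested singles are a separate verdict the user can exclude
  ids2 <- rbind(ids, mk_id("r5", "undigested_single", pA = "pX", gene = "gA"))
  class(ids2) <- c("identification_tab", "data.frame")
  with_und <- tabulate_promoters(ids2, cd$design)
  without <- tabulate_promoters(ids2, cd$design,
                                include = c("multigene", "digested_single"))
  expect_equal(sum(with_und$count) - sum(without$count), 1)
})
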