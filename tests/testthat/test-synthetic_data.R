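test_that("promoter draws are uniform per slot over many assemblies", {
  w <- the_world()
  n <- 10000
  draws <- combilib:::with_seed(11, {
    replicate(n, simulate_assembly(w, "multigene")$promoter_choice)
  })
  # 3-sigma band per cell, Bonferroni-adjusted for the 30 simultaneous cells
  z <- qnorm(1 - pnorm(-3) / 30)
  tol <- z * sqrt(0.1 * 0.9 / n)
  for (g in seq_len(nrow(draws))) {
    counts <- table(factor(draws[g, ], levels = names(w$design$parts)))
    expect_true(all(abs(counts / n - 0.1) < tol))
    expect_gt(chisq.test(counts)$p.value, 1e-3)   # per-slot uniformity
  }
  # and the sequence-level path agrees with its own truth record
  inst <- simulate_assembly(w, "multigene", seed = 3)
  expect_identical(nchar(inst$sequence),
                   sum(nchar(vapply(w$design$parts[inst$promoter_choice],
                                    `[[`, "", "sequence"))) +
                     sum(nchar(vapply(w$design$units, `[[`, "", "sequence"))))
})

test_that("degenerate and biased draws behave as stated", {
  d <- tiny_design()
  d1 <- d
  d1$slots <- list(gA = "pS1", gB = "pM1")
  a <- simulate_assembly(d1, "multigene", seed = 1)
  b <- simulate_assembly(d1, "multigene", seed = 999)
  expect_identical(a$sequence, b$sequence)   # single candidate: deterministic

  bias <- list(gA = c(pW1 = 1), gB = c(pW1 = 1))
  for (s in 1:5) {
    inst <- simulate_assembly(d, "multigene", bias = bias, seed = s)
    expect_identical(unname(inst$promoter_choice), c("pW1", "pW1"))
  }
  expect_error(simulate_assembly(d, "junk_kind"))
})

test_that("digest size selection honours the printed windows inclusively", {
  mk <- function(kind, gene, len)
    list(kind = kind, gene = gene, sequence = strrep("A", len))
  expect_false(is.na(digest_and_select(mk("multigene", NA, 5616))))
  expect_true(is.na(digest_and_select(mk("multigene", NA, 5615))))
  expect_false(is.na(digest_and_select(mk("multigene", NA, 6117))))
  expect_true(is.na(digest_and_select(mk("multigene", NA, 6118))))
  expect_false(is.na(digest_and_select(mk("single_gene", "pclA", 2600))))
  expect_true(is.na(digest_and_select(mk("single_gene", "pclA", 2548))))
  expect_error(digest_and_select(mk("single_gene", "gX", 2000)), "no size window")
})

test_that("digest acceptance is monotone in window width", {
  lens <- seq(5000, 6500, by = 37)
  insts <- lapply(lens, function(l)
    list(kind = "multigene", gene = NA, sequence = strrep("A", l)))
  acc <- function(w) sum(!is.na(vapply(insts, digest_and_select, "",
                                       windows = w)))
  narrow <- size_windows(list(multigene = c(5700, 6000)))
  wide <- size_windows(list(multigene = c(5616, 6117)))
  wider <- size_windows(list(multigene = c(5000, 6500)))
  expect_true(acc(narrow) <= acc(wide))
  expect_true(acc(wide) <= acc(wider))
  expect_equal(acc(wider), length(lens))
})

test_that("default world geometry lands every fragment in its window", {
  w <- the_world()
  for (s in 1:25) {
    mg <- simulate_assembly(w, "multigene", seed = s)
    expect_false(is.na(digest_and_select(mg)))
    g <- sample(names(w$design$slots), 1)
    sg <- simulate_assembly(w, "single_gene", gene = g, seed = s + 100)
    expect_false(is.na(digest_and_select(sg)))
  }
})

test_that("error-free reads equal the fragment or its reverse complement", {
  frag <- c(f1 = combilib:::random_dna(300))
  rr <- simulate_reads(frag, error_model(0, 0, 0), n_reads = 20, seed = 4)
  for (i in seq_along(rr$reads)) {
    obs <- rr$reads[[i]]
    expect_true(obs == frag[[1]] || obs == combilib:::revcomp(frag[[1]]))
    expect_identical(obs == frag[[1]], rr$truth$strand[i] == "+")
  }
})

test_that("substitution-only error rate reproduces the target identity", {
  p <- 0.05
  n <- 1000
  len <- 500
  frag <- combilib:::with_seed(8, combilib:::random_dna(len))
  rr <- simulate_reads(setNames(frag, "f"), error_model(p, 0, 0),
                       n_reads = n, seed = 21)
  base <- strsplit(frag, "")[[1]]
  ident <- vapply(seq_len(n), function(i) {
    s <- rr$reads[[i]]
    if (rr$truth$strand[i] == "-") s <- combilib:::revcomp(s)
    mean(strsplit(s, "")[[1]] == base)
  }, 0)
  se <- sqrt(p * (1 - p) / (n * len))
  expect_lt(abs(mean(ident) - (1 - p)), 3 * se)
})

test_that("read simulation is deterministic and fully truth-tracked", {
  w <- the_world()
  r1 <- simulate_run(w, n_reads = 25, seed = 13)
  r2 <- simulate_run(w, n_reads = 25, seed = 13)
  expect_identical(r1, r2)
  expect_identical(names(r1$reads), r1$truth$read_id)
  expect_false(anyDuplicated(r1$truth$read_id) > 0)
  # strand balance at larger n
  r3 <- simulate_run(w, n_reads = 400, model = error_model(0, 0, 0),
                     proportions = c(multigene = 0, single_gene = 1,
                                     undigested_single = 0, contaminant = 0),
                     seed = 17)
  fwd <- mean(r3$truth$strand == "+")
  expect_lt(abs(fwd - 0.5), 3 * sqrt(0.25 / 400))
  expect_error(simulate_reads(list(), error_model()), "empty")
})

test_that("indel rates shift read length as expected", {
  frag <- setNames(combilib:::with_seed(9, combilib:::random_dna(2000)), "f")
  rr_ins <- simulate_reads(frag, error_model(0, 0.05, 0), n_reads = 200,
                           seed = 31)
  rr_del <- simulate_reads(frag, error_model(0, 0, 0.05), n_reads = 200,
                           seed = 32)
  expect_gt(mean(nchar(rr_ins$reads)), 2000 * 1.03)
  expect_lt(mean(nchar(rr_del$reads)), 2000 * 0.97)
})

test_that("reads and truth write as plain-text files", {
  w <- the_world()
  rr <- simulate_run(w, n_reads = 5, seed = 2)
  fa <- tempfile(fileext = ".fasta")
  fq <- tempfile(fileext = ".fastq")
  tt <- tempfile(fileext = ".tsv")
  write_reads(rr$reads, fa)
  write_reads(rr$reads, fq, format = "fastq")
  write_truth(rr$truth, tt)
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(unname(as.character(back)), unname(rr$reads))
  expect_identical(readLines(fq)[2], unname(rr$reads[1]))
  tr <- read.delim(tt)
  expect_identical(tr$read_id, rr$truth$read_id)
})
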