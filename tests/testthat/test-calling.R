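# Demultiplexing, primer trimming, library mapping, de novo calling and
# replicate confirmation.

fake_reads <- function(seqs, ids = sprintf("r%02d", seq_along(seqs)),
                       replicate = 1L)
  data.frame(read_id = ids, replicate = replicate, sequence = seqs,
             stringsAsFactors = FALSE)

test_that("reads demultiplex to the unique nearest barcode with a tie rule", {
  manifest <- data.frame(barcode = c("AAAAAAAACCCCCCCC", "GGGGGGGGTTTTTTTT"),
                         animal_id = c("an1", "an2"))
  payload <- "ACGTACGTACGTACGT"
  rd <- fake_reads(c(
    paste0("AAAAAAAACCCCCCCC", payload),          # exact
    paste0("TAAAAAAACCCCCCCC", payload),          # 1 mismatch, unique
    paste0(revcomp(paste0("GGGGGGGGTTTTTTTT", payload)))))  # reverse strand
  out <- demultiplex(rd, manifest, max_mismatch = 1)
  expect_equal(out$animal_id, c("an1", "an1", "an2"))
  # equidistant read -> unassigned
  half <- paste0("AAAAAAAATTTTTTTT", payload)
  out2 <- demultiplex(fake_reads(half), manifest, max_mismatch = 7)
  expect_true(is.na(out2$animal_id))
  # every read lands in exactly one bin
  expect_equal(nrow(out), 3)
  # manifest separation precondition
  close_manifest <- data.frame(barcode = c("AAAAAAAAAAAAAAAA",
                                           "AAAAAAAAAAAAAAAT"),
                               animal_id = c("x", "y"))
  expect_error(demultiplex(rd, close_manifest, max_mismatch = 1), "rejected")
})

test_that("primer trimming excises the insert and normalizes strand", {
  fwd <- "CTCAGATTCTCCCCAGACGCG"
  rev <- "GGGGTGAAGACAYATTTGGAC"   # degenerate Y respected
  insert <- paste(rep("ACGT", 50), collapse = "")
  read <- paste0("TTTTTTTTTTTTTTTT", fwd, insert, revcomp(rev))
  out <- trim_primers(read, fwd, rev)
  expect_equal(out$trimmed, insert)
  out_rc <- trim_primers(revcomp(read), fwd, rev)
  expect_equal(out_rc$trimmed, insert)
  expect_equal(out_rc$orientation, "rev")
  # missing forward motif -> untrimmable
  broken <- paste0("TTTTTTTTTTTTTTTT", insert, revcomp(rev))
  expect_true(is.na(trim_primers(broken, fwd, rev)$trimmed))
})

test_that("library mapping assigns unique near-identical hits and leaves novels unused", {
  set.seed(31)
  lib <- setNames(vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = ""),
    ""), c("al1", "al2", "al3"))
  r1 <- lib[["al1"]]
  substr(r1, 500, 500) <- if (substr(r1, 500, 500) == "A") "C" else "A"
  res <- map_to_library(c(lib[["al2"]], r1), lib, min_identity = 0.98)
  expect_equal(res$allele, c("al2", "al1"))
  expect_equal(res$identity[1], 1.0)
  expect_equal(res$identity[2], 0.999)
  novel <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                 collapse = "")
  res2 <- map_to_library(novel, lib)
  expect_true(is.na(res2$allele))
  expect_equal(res2$unused, 1L)
  # empty library: everything unused, not an error
  res3 <- map_to_library(c(r1, novel), character(0))
  expect_equal(res3$unused, 1:2)
  expect_error(map_to_library(r1, c(a = "ACGT", b = "ACGT")), "non-redundant")
})

test_that("de novo calling recovers a novel allele from noisy reads", {
  set.seed(17)
  truth <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                 collapse = "")
  exact <- rep(truth, 20)
  dn <- denovo_call(exact, min_cluster_size = 3)
  expect_equal(dn$sequence, truth)
  expect_equal(dn$support, 20)
  noisy <- mhcfkit:::inject_errors(rep(truth, 20), 0.005)
  dn2 <- denovo_call(noisy, min_cluster_size = 3)
  expect_equal(dn2$sequence, truth)
  # single stray read below the support threshold yields nothing
  dn3 <- denovo_call(truth, min_cluster_size = 3)
  expect_equal(nrow(dn3), 0)
})

test_that("de novo calling phases a heterozygous read mixture", {
  set.seed(23)
  a <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
  b <- a
  for (p in c(50, 220, 430)) substr(b, p, p) <- chartr("ACGT", "CGTA",
                                                       substr(b, p, p))
  reads <- mhcfkit:::inject_errors(c(rep(a, 25), rep(b, 25)), 0.005)
  dn <- denovo_call(reads, min_cluster_size = 5)
  expect_setequal(dn$sequence, c(a, b))
})

test_that("replicate confirmation distinguishes confirmed, provisional and chimeric calls", {
  set.seed(41)
  x <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  y <- x
  for (p in c(40, 80, 310, 350))
    substr(y, p, p) <- chartr("ACGT", "GTAC", substr(y, p, p))
  z <- x
  substr(z, 150, 150) <- chartr("ACGT", "TACG", substr(z, 150, 150))
  mosaic <- paste0(substr(x, 1, 200), substring(y, 201))  # x 5' + y 3'
  cands <- data.frame(
    replicate = c(1, 2, 1, 2, 1, 1, 2),
    sequence = c(x, x, y, y, z, mosaic, mosaic),
    support = c(30, 28, 25, 26, 7, 6, 6), stringsAsFactors = FALSE)
  out <- confirm_alleles(cands)
  expect_equal(out$status[out$sequence == x], "confirmed_novel")
  expect_equal(out$status[out$sequence == y], "confirmed_novel")
  expect_equal(out$status[out$sequence == z], "provisional")
  expect_equal(out$status[out$sequence == mosaic], "rejected_artifact")
  expect_true(all(out$supporting_replicates[out$status == "confirmed_novel"] >= 2))
})

test_that("noiseless cohorts are recovered exactly with an empty library", {
  for (seed in c(101, 202)) {
    rep <- make_test_repertoire(seed = seed, allele_count = 5)
    coh <- generate_cohort(rep, n_animals = 5)
    sim <- simulate_amplicon_reads(coh, rep, depth = 8, error_rate = 0,
                                   chimera_rate = 0)
    calls <- call_alleles(sim$reads, sim$manifest, sim$primers,
                          min_cluster_size = 3)
    seq_of <- setNames(rep$alleles$sequence, rep$alleles$allele_id)
    for (a in coh$animals$animal_id) {
      truth <- sort(unique(unname(
        seq_of[coh$genotypes$allele_id[coh$genotypes$animal_id == a]])))
      called <- sort(calls$sequence[calls$animal_id == a &
                                    calls$status == "confirmed_novel"])
      expect_identical(called, truth, info = paste("seed", seed, a))
    }
  }
})

test_that("known-library matches are reported as known_match calls", {
  rep <- make_test_repertoire(seed = 55, allele_count = 4)
  coh <- generate_cohort(rep, n_animals = 4)
  sim <- simulate_amplicon_reads(coh, rep, depth = 8, error_rate = 0)
  lib <- setNames(rep$alleles$sequence, rep$alleles$allele_id)
  calls <- call_alleles(sim$reads, sim$manifest, sim$primers, library = lib,
                        min_cluster_size = 3)
  expect_true(all(calls$status == "known_match"))
  expect_true(all(!is.na(calls$allele)))
  expect_true(all(calls$read_support > 0))
})

test_that("one-gene non-chimeric animals never yield more than two confirmed calls", {
  rep <- make_test_repertoire(seed = 91, allele_count = 8)
  coh <- generate_cohort(rep, n_animals = 8)
  sim <- simulate_amplicon_reads(coh, rep, depth = 20, error_rate = 0.005,
                                 chimera_rate = 0.05, seed = 2)
  calls <- call_alleles(sim$reads, sim$manifest, sim$primers)
  acc <- calls[calls$status %in% c("known_match", "confirmed_novel"), ]
  per_animal <- table(acc$animal_id)
  expect_true(all(per_animal <= 2))
})
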