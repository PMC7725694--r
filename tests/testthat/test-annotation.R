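# Indel detection, ORF classification, isoform labelling, event catalogue
# and paralogue assignment.

test_that("alignment against the reference reports single indel blocks", {
  ref <- mhcf_reference("nwm_marmoset")
  expect_equal(nrow(align_and_detect(ref$seq, ref)$events), 0)
  em <- ref$exon_map
  e3 <- em[em$exon == "3", ]
  # 38-nt deletion inside exon 3: one frameshifting block
  tx38 <- paste0(substr(ref$seq, 1, e3$end - 38), substring(ref$seq, e3$end + 1))
  ev <- align_and_detect(tx38, ref)$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$size_nt, 38)
  expect_equal(ev$frame_effect, "frameshift")
  expect_match(ev$exon_context, "exon 3")
  # 63-nt deletion: in frame
  tx63 <- paste0(substr(ref$seq, 1, e3$end - 63), substring(ref$seq, e3$end + 1))
  ev63 <- align_and_detect(tx63, ref)$events
  expect_equal(ev63$size_nt, 63)
  expect_equal(ev63$frame_effect, "in_frame")
  # deletions report 1-based inclusive coordinates
  expect_equal(ev63$size_nt, ev63$end - ev63$start + 1)
  # unrelated sequence fails the comparability floor
  junk <- with(list(), paste(rep("ACGT", 260), collapse = ""))
  expect_error(align_and_detect(junk, ref), "not comparable")
})

test_that("ORF classification separates functional alleles from pseudogenes", {
  ref <- mhcf_reference("nwm_marmoset")
  intact <- classify_orf(ref$seq, reference = ref)
  expect_equal(intact$status, "functional")
  expect_equal(intact$name_suffix, "")
  expect_true(intact$exon7_absent)
  em <- ref$exon_map
  # 2-nt deletion in exon 3 -> frameshift -> pseudogene, suffix N
  at <- em$start[em$exon == "3"] + 40
  fs <- paste0(substr(ref$seq, 1, at - 1), substring(ref$seq, at + 2))
  afs <- classify_orf(fs, reference = ref)
  expect_equal(afs$status, "pseudogene")
  expect_equal(afs$name_suffix, "N")
  expect_true("frameshift" %in% afs$reasons$type)
  # engineered in-frame stop inside exon 4 -> premature_stop located in exon 4
  e4 <- em$start[em$exon == "4"] + 27
  stopifnot((e4 - 1) %% 3 == 0)
  ps <- paste0(substr(ref$seq, 1, e4 - 1), "TAA", substring(ref$seq, e4 + 3))
  aps <- classify_orf(ps, reference = ref)
  expect_equal(aps$status, "pseudogene")
  rs <- aps$reasons[aps$reasons$type == "premature_stop", ]
  expect_equal(rs$exon, "4")
  expect_error(classify_orf(sub("^ATG", "CTG", ref$seq)), "initiator")
})

test_that("ORF status is invariant under random synonymous edits", {
  ref <- mhcf_reference("owm")
  codons <- substring(ref$seq, seq(1, nchar(ref$seq) - 2, 3),
                      seq(3, nchar(ref$seq), 3))
  gc <- Biostrings::GENETIC_CODE
  syn_of <- split(names(gc), gc)
  set.seed(99)
  for (i in 1:300) {
    j <- sample(2:(length(codons) - 1), 1)
    alts <- setdiff(syn_of[[gc[codons[j]]]], codons[j])
    if (!length(alts)) next
    edited <- codons
    edited[j] <- sample(alts, 1)
    expect_equal(classify_orf(paste(edited, collapse = ""))$status,
                 "functional")
  }
})

test_that("frameshift pseudogene verdicts co-occur with a premature stop in forced translation", {
  ref <- mhcf_reference("owm")
  set.seed(7)
  for (i in 1:10) {
    at <- sample(200:800, 1)
    fs <- paste0(substr(ref$seq, 1, at - 1), substring(ref$seq, at + 1))
    a <- classify_orf(fs, reference = ref)
    expect_equal(a$status, "pseudogene")
    expect_true(any(a$reasons$type %in% c("premature_stop",
                                          "no_terminal_stop")),
                info = paste("deletion at", at))
  }
})

test_that("isoform labelling recognises intron retention, truncation and exon skip", {
  ref <- mhcf_reference("nwm_marmoset")
  menu <- isoform_event_menu("nwm_marmoset")
  introns <- c(intron1 = mhcfkit:::intron1_seq(130))
  ret <- simulate_isoforms(ref$seq, menu[menu$event_id == "ret_intron1_130", ])
  ci <- classify_isoform(ret$sequence, ref$seq, ref$exon_map,
                         intron_library = introns)
  expect_equal(ci$events$kind, "intron_retention")
  expect_equal(ci$events$size_nt, 130)
  expect_equal(ci$annotation$status, "pseudogene")
  stop_reason <- ci$annotation$reasons[
    ci$annotation$reasons$type == "premature_stop", ]
  expect_equal(nrow(stop_reason), 1)   # early stop from the frame shift
  tr <- simulate_isoforms(ref$seq, menu[menu$event_id == "del_first61_exon2", ])
  ci2 <- classify_isoform(tr$sequence, ref$seq, ref$exon_map)
  expect_equal(ci2$events$label, "First part exon 2")
  expect_equal(ci2$events$size_nt, 61)
  sk <- simulate_isoforms(ref$seq, menu[menu$event_id == "skip_exon5", ])
  ci3 <- classify_isoform(sk$sequence, ref$seq, ref$exon_map)
  expect_equal(ci3$events$kind, "exon_skip")
  e5len <- ref$exon_map$length[ref$exon_map$exon == "5"]
  expect_equal(ci3$events$frame_effect,
               if (e5len %% 3 == 0) "in_frame" else "frameshift")
})

test_that("every isoform menu event round-trips through detection with its size and frame", {
  for (clade in c("owm", "nwm_marmoset")) {
    ref <- mhcf_reference(clade)
    menu <- isoform_event_menu(clade)
    introns <- c(intron1 = mhcfkit:::intron1_seq(130))
    for (k in seq_len(nrow(menu))) {
      iso <- simulate_isoforms(ref$seq, menu[k, ])
      ci <- classify_isoform(iso$sequence, ref$seq, ref$exon_map,
                             intron_library = introns)
      expect_equal(nrow(ci$events), 1, info = menu$event_id[k])
      expect_equal(ci$events$size_nt, menu$size[k], info = menu$event_id[k])
      expect_equal(ci$events$frame_effect,
                   if (menu$size[k] %% 3 == 0) "in_frame" else "frameshift",
                   info = menu$event_id[k])
    }
  }
})

test_that("recurrent events are catalogued at three animals and artifacts set aside", {
  ev <- data.frame(
    animal_id = c("a1", "a2", "a3", "a4", "a5"),
    kind = c("deletion", "deletion", "deletion", "deletion", "insertion"),
    start = c(65, 65, 65, 330, 997),
    end = c(182, 182, 182, 392, 996),
    size_nt = c(118, 118, 118, 63, 18),
    allele = c("x04:01", "x04:02N", "x06:01", "x04:02N", "x06:02"),
    stringsAsFactors = FALSE)
  tab <- catalogue_events(ev, min_animals = 3)
  expect_equal(nrow(tab$recurrent), 1)
  expect_equal(tab$recurrent$n_animals, 3)
  expect_equal(tab$recurrent$size_nt, 118)
  expect_match(tab$recurrent$carriers, "x04:01")
  expect_equal(nrow(tab$artifacts), 2)
  empty <- catalogue_events(ev[0, ])
  expect_equal(nrow(empty$recurrent), 0)
  expect_equal(nrow(empty$artifacts), 0)
})

test_that("transcripts are assigned to genomic paralogues with margin and novelty rules", {
  base <- mhcf_reference("nwm_marmoset")$seq
  set.seed(12)
  mutate_at <- function(s, k) {
    for (p in sample(nchar(s), k))
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    s
  }
  genes <- c(F1 = mutate_at(base, 60), F2 = mutate_at(base, 60),
             F3 = mutate_at(base, 60), F4 = base,
             F5 = mutate_at(base, 3))
  # identical to the F4 CDS
  expect_equal(assign_gene(base, genes)$status, "ambiguous")  # F4 vs near-F5
  genes2 <- genes[c("F1", "F2", "F3", "F4")]
  a <- assign_gene(base, genes2)
  expect_equal(a$gene, "F4")
  expect_equal(a$identity, 1)
  # F1 minus a 38-nt deletion still goes to F1 (identity excludes gaps)
  tx <- paste0(substr(genes2[["F1"]], 1, 600), substring(genes2[["F1"]], 639))
  expect_equal(assign_gene(tx, genes2)$gene, "F1")
  # a transcript below threshold against all genes founds the next gene
  novel <- mutate_at(base, 80)
  n <- assign_gene(novel, genes2)
  expect_equal(n$status, "new_gene")
  expect_equal(n$gene, "F5")
  expect_error(assign_gene(base, character(0)), "empty")
})

test_that("clade structural variants are recovered against the great-ape reference", {
  ga <- mhcf_reference("great_ape")
  owm <- mhcf_reference("owm")
  ev <- align_and_detect(owm$seq, ga, min_identity = 0.7)$events
  ins <- ev[ev$kind == "insertion", ]
  expect_equal(ins$size_nt, 6)
  expect_match(ins$exon_context, "exon 2")
  mar <- mhcf_reference("nwm_marmoset")
  evm <- align_and_detect(mar$seq, ga, min_identity = 0.7)$events
  expect_setequal(evm$size_nt[evm$kind == "deletion"], c(9, 12))
  expect_setequal(evm$size_nt[evm$kind == "insertion"], c(6, 9))
  expect_true(all(evm$frame_effect == "in_frame"))
})
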