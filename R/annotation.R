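#' @name annotation
#' @title Indel detection, ORF classification and paralogue assignment
#'
#' @description
#' Transcripts are globally aligned to a reference CDS with affine gap
#' penalties that favour single long gap blocks (match +1, mismatch -2, gap
#' open -5, gap extend -1); each maximal gap is reported as one indel event
#' with event-catalogue exon context ("First part exon 2", "Whole exon 5",
#' "2 nt exon 2-exon 3", ...). Gap placement inside repeats is normalized to
#' the 5'-most equivalent position so that reported coordinates are
#' deterministic. ORFs are classified functional vs pseudogene (premature
#' stop / frameshift; the "N" name suffix), splice isoforms are labelled
#' (intron retention against a supplied intron library, whole-exon skips,
#' exon-start truncations), and events recurring in three or more animals
#' are catalogued with smaller groups set aside as putative PCR or
#' sequencing artifacts.
NULL

# shift every gap run to its 5'-most score-equivalent position
normalize_gaps_left <- function(ref, qry) {
  shift_one <- function(gapped, other) {
    g <- strsplit(gapped, "")[[1]]
    o <- strsplit(other, "")[[1]]
    repeat {
      moved <- FALSE
      r <- rle(g == "-")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        i <- starts[k]; j <- ends[k]
        while (i > 1 && g[i - 1] != "-" && o[i - 1] == o[j]) {
          g[j] <- g[i - 1]
          g[i - 1] <- "-"
          i <- i - 1; j <- j - 1
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    paste(g, collapse = "")
  }
  qry2 <- shift_one(qry, ref)   # deletions: gaps in query, bases in ref
  ref2 <- shift_one(ref, qry2)  # insertions: gaps in ref
  list(ref = ref2, qry = qry2)
}

# event-catalogue context label for a reference interval
exon_context_label <- function(start, end, exon_map, kind = "deletion") {
  em <- exon_map
  e1 <- em$exon[em$start <= start & em$end >= start]
  e2 <- em$exon[em$start <= end & em$end >= end]
  if (kind %in% c("insertion", "intron_retention")) {
    at_boundary <- any(em$end == end)
    e <- em$exon[em$end == end]
    return(if (at_boundary) paste0("Behind exon ", e[1])
           else paste0("exon ", e1[1]))
  }
  if (!length(e1) || !length(e2)) return("outside exon map")
  if (e1 == e2) {
    row <- em[em$exon == e1, ]
    if (start == row$start && end == row$end) return(paste0("Whole exon ", e1))
    if (start == row$start) return(paste0("First part exon ", e1))
    if (end == row$end) return(paste0("Last part exon ", e1))
    return(paste0("exon ", e1))
  }
  nt_first <- em$end[em$exon == e1] - start + 1
  paste0(nt_first, " nt exon ", e1, "-exon ", e2)
}

#' Align a transcript to a reference and report indel events
#'
#' Global affine-gap alignment; each maximal gap becomes one event with
#' 1-based inclusive coordinates in reference space, exon context from the
#' reference exon map, and its frame effect (in-frame iff size mod 3 = 0).
#' Gaps are left-normalized before coordinates are read off.
#'
#' @param transcript DNA string.
#' @param reference a `mhcf_reference` or any list with `seq` and
#'   `exon_map`.
#' @param min_identity comparability floor on gap-excluded identity
#'   (default 0.7).
#' @return list with `events` (data frame kind/start/end/size_nt/
#'   exon_context/frame_effect/inserted_seq), `identity`, and the aligned
#'   `ref`/`qry` strings.
#' @export
align_and_detect <- function(transcript, reference, min_identity = 0.7) {
  stopifnot(nchar(transcript) > 0, nchar(reference$seq) > 0)
  pa <- Biostrings::pairwiseAlignment(
    transcript, reference$seq, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 1)
  qry <- as.character(Biostrings::alignedPattern(pa))
  ref <- as.character(Biostrings::alignedSubject(pa))
  ident <- Biostrings::nmatch(pa) /
    (Biostrings::nmatch(pa) + Biostrings::nmismatch(pa))
  if (ident < min_identity)
    stop(sprintf("not comparable: identity %.3f below floor %.2f",
                 ident, min_identity))
  nz <- normalize_gaps_left(ref, qry)
  ref <- nz$ref; qry <- nz$qry
  rc <- strsplit(ref, "")[[1]]
  qc <- strsplit(qry, "")[[1]]
  refpos <- cumsum(rc != "-")            # reference coordinate per column
  events <- list()
  add_run <- function(gapped, kind) {
    r <- rle(gapped == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i <- starts[k]; j <- ends[k]
      if (kind == "deletion") {
        s <- refpos[i]; e <- refpos[j]
        events[[length(events) + 1]] <<- data.frame(
          kind = "deletion", start = s, end = e, size_nt = e - s + 1,
          inserted_seq = "", stringsAsFactors = FALSE)
      } else {
        after <- if (i == 1) 0L else refpos[i - 1]
        events[[length(events) + 1]] <<- data.frame(
          kind = "insertion", start = after + 1L, end = after,
          size_nt = j - i + 1L,
          inserted_seq = paste(qc[i:j], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  add_run(qc, "deletion")
  add_run(rc, "insertion")
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(0), start = integer(0), end = integer(0),
               size_nt = integer(0), inserted_seq = character(0),
               stringsAsFactors = FALSE)
  if (nrow(ev)) {
    ev <- ev[order(ev$start), , drop = FALSE]
    # a gap inside a repeat has several score-equivalent placements; after
    # left-normalization, snap a deletion to an exon boundary when one of
    # its equivalent placements is flush with it (catalogue labels such
    # as "First part exon 2" depend on the boundary placement)
    refseq <- strsplit(gsub("-", "", ref), "")[[1]]
    em <- reference$exon_map
    for (k in which(ev$kind == "deletion")) {
      s <- ev$start[k]; e <- ev$end[k]
      r_max <- 0L
      while (e + r_max + 1 <= length(refseq) &&
             refseq[s + r_max] == refseq[e + r_max + 1]) r_max <- r_max + 1L
      if (r_max > 0) {
        snap <- which(vapply(0:r_max, function(d)
          (s + d) %in% em$start || (e + d) %in% em$end, TRUE)) - 1L
        if (length(snap) && snap[1] > 0) {
          ev$start[k] <- s + snap[1]
          ev$end[k] <- e + snap[1]
        }
      }
    }
    ev$exon_context <- vapply(seq_len(nrow(ev)), function(k)
      exon_context_label(ev$start[k],
                         if (ev$kind[k] == "deletion") ev$end[k]
                         else ev$start[k] - 1L,
                         reference$exon_map, ev$kind[k]), "")
    ev$frame_effect <- ifelse(ev$size_nt %% 3 == 0, "in_frame", "frameshift")
    rownames(ev) <- NULL
  } else {
    ev$exon_context <- character(0)
    ev$frame_effect <- character(0)
  }
  list(events = ev, identity = ident, ref = ref, qry = qry)
}

#' Classify a transcript ORF as functional or pseudogene
#'
#' Translates in the reading frame of the initiator codon. A stop before
#' the final codon is a premature stop (located by exon when a reference is
#' supplied, via the alignment); a net indel length not divisible by 3
#' upstream (from the events against the reference) is a frameshift. The
#' transcript is functional iff no reasons accumulate, and then carries no
#' name suffix; otherwise the suffix is "N".
#'
#' @param transcript DNA string beginning at the initiator codon.
#' @param reference optional `mhcf_reference`-like list enabling frameshift
#'   detection and exon localisation of stops.
#' @param exon_map optional exon map used when no reference is given
#'   (transcript coordinates).
#' @return object of class `mhcf_annotation`: list with `status`
#'   (`functional`/`pseudogene`), `reasons` (data frame type/exon/codon/
#'   position), `exon7_absent` (TRUE), `name_suffix`.
#' @export
classify_orf <- function(transcript, reference = NULL, exon_map = NULL) {
  if (substr(transcript, 1, 3) != "ATG")
    stop("annotation error: transcript does not start at an initiator codon")
  reasons <- list()
  events <- NULL
  if (!is.null(reference)) {
    ad <- align_and_detect(transcript, reference)
    events <- ad$events
    if (is.null(exon_map)) exon_map <- reference$exon_map
    if (nrow(events)) {
      net <- cumsum(ifelse(events$kind == "deletion", -events$size_nt,
                           events$size_nt))
      fs <- which(events$size_nt %% 3 != 0)
      for (k in fs)
        reasons[[length(reasons) + 1]] <- data.frame(
          type = "frameshift", exon = events$exon_context[k],
          codon = NA_integer_, position = events$start[k],
          stringsAsFactors = FALSE)
    }
  }
  n_full <- nchar(transcript) %/% 3
  codons <- substring(transcript, seq(1, n_full * 3, 3) ,
                      seq(3, n_full * 3, 3))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_idx <- which(aa == "*")[1]
  premature <- !is.na(stop_idx) && stop_idx < n_full
  if (premature) {
    pos_tx <- (stop_idx - 1) * 3 + 1
    exon <- NA_character_
    if (!is.null(reference)) {
      # map transcript position to reference coordinates through the events
      ref_pos <- pos_tx
      if (!is.null(events) && nrow(events)) {
        for (k in seq_len(nrow(events))) {
          ev <- events[k, ]
          if (ev$kind == "deletion" && ev$start <= ref_pos)
            ref_pos <- ref_pos + ev$size_nt
          if (ev$kind == "insertion" && ev$start <= ref_pos)
            ref_pos <- ref_pos - min(ev$size_nt, ref_pos - ev$start + 1)
        }
      }
      em <- reference$exon_map
      hit <- em$exon[em$start <= ref_pos & em$end >= ref_pos]
      if (length(hit)) exon <- hit[1]
    } else if (!is.null(exon_map)) {
      hit <- exon_map$exon[exon_map$start <= pos_tx & exon_map$end >= pos_tx]
      if (length(hit)) exon <- hit[1]
    }
    reasons[[length(reasons) + 1]] <- data.frame(
      type = "premature_stop", exon = exon, codon = stop_idx,
      position = pos_tx, stringsAsFactors = FALSE)
  }
  if (is.na(stop_idx))
    reasons[[length(reasons) + 1]] <- data.frame(
      type = "no_terminal_stop", exon = NA_character_, codon = NA_integer_,
      position = NA_integer_, stringsAsFactors = FALSE)
  reasons <- if (length(reasons)) do.call(rbind, reasons) else
    data.frame(type = character(0), exon = character(0),
               codon = integer(0), position = integer(0),
               stringsAsFactors = FALSE)
  status <- if (nrow(reasons)) "pseudogene" else "functional"
  structure(list(status = status, reasons = reasons, exon7_absent = TRUE,
                 name_suffix = if (status == "pseudogene") "N" else ""),
            class = "mhcf_annotation")
}

#' @export
print.mhcf_annotation <- function(x, ...) {
  cat("ORF status:", x$status,
      if (nzchar(x$name_suffix)) paste0("(name suffix \"", x$name_suffix, "\")"),
      "\n")
  if (nrow(x$reasons)) print(x$reasons)
  invisible(x)
}

#' Label the splice events distinguishing an isoform from its allele
#'
#' Insertions matching a supplied intron adjacent to its exon boundary are
#' intron retentions; deletions spanning exactly one whole exon are exon
#' skips; deletions flush with an exon 5' end are "First part exon k"
#' truncations. Frame and stop consequences are computed as in
#' [classify_orf()].
#'
#' @param transcript isoform sequence.
#' @param full_length the full-length allele CDS it derives from.
#' @param exon_map exon map of the allele.
#' @param intron_library optional named character vector of intron
#'   sequences (e.g. `c(intron1 = ...)`).
#' @return list with `events` (with `label` column), `annotation` (the
#'   [classify_orf()] result).
#' @export
classify_isoform <- function(transcript, full_length, exon_map,
                             intron_library = NULL) {
  ref <- list(seq = full_length, exon_map = exon_map)
  ad <- align_and_detect(transcript, ref)
  ev <- ad$events
  if (nrow(ev)) {
    ev$label <- ev$exon_context
    for (k in seq_len(nrow(ev))) {
      if (ev$kind[k] == "insertion" && !is.null(intron_library)) {
        # gaps are left-normalized, so an intron retained at an exon 3' end
        # may be reported a few positions 5' of the junction with its
        # sequence rotated; rotations of the same-length intron prefix are
        # alignment-equivalent placements of the same insertion.
        n <- nchar(ev$inserted_seq[k])
        hit <- vapply(intron_library, function(intr) {
          ip <- substr(intr, 1, n)
          nchar(ip) == n && grepl(ev$inserted_seq[k], paste0(ip, ip),
                                  fixed = TRUE)
        }, TRUE)
        at <- ev$start[k] - 1L
        at_boundary <- any(exon_map$end >= at & exon_map$end <= at + n)
        if (any(hit) && at_boundary) {
          ev$kind[k] <- "intron_retention"
          ev$label[k] <- paste("Intron", sub("\\D*(\\d+).*", "\\1",
                                             names(intron_library)[hit][1]))
        }
      }
      if (ev$kind[k] == "deletion" &&
          startsWith(ev$exon_context[k], "Whole exon")) {
        ev$kind[k] <- "exon_skip"
        ev$label[k] <- ev$exon_context[k]
      }
    }
  } else {
    ev$label <- character(0)
  }
  ann <- classify_orf(transcript, reference = ref)
  list(events = ev, annotation = ann)
}

#' Catalogue recurrent indel/splice events across animals
#'
#' Events are grouped by (kind, start, end, size); groups seen in at least
#' `min_animals` distinct animals form the recurrent-event table (with
#' carrier alleles), smaller groups are reported separately as putative PCR
#' or sequencing artifacts.
#'
#' @param events data frame with columns `animal_id`, `kind`, `start`,
#'   `end`, `size_nt` and optionally `allele`, `exon_context`.
#' @param min_animals recurrence threshold (default 3).
#' @return list with `recurrent` and `artifacts` data frames (position
#'   range, size, context, carrier alleles, n_animals).
#' @export
catalogue_events <- function(events, min_animals = 3) {
  empty <- data.frame(kind = character(0), start = integer(0),
                      end = integer(0), size_nt = integer(0),
                      exon_context = character(0), n_animals = integer(0),
                      carriers = character(0), stringsAsFactors = FALSE)
  if (is.null(events) || nrow(events) == 0)
    return(list(recurrent = empty, artifacts = empty))
  need_cols(events, c("animal_id", "kind", "start", "end", "size_nt"),
            "events")
  if (is.null(events$allele)) events$allele <- NA_character_
  if (is.null(events$exon_context)) events$exon_context <- ""
  key <- paste(events$kind, events$start, events$end, events$size_nt,
               sep = "|")
  rows <- lapply(split(seq_len(nrow(events)), key), function(idx) {
    e <- events[idx, ]
    data.frame(kind = e$kind[1], start = e$start[1], end = e$end[1],
               size_nt = e$size_nt[1], exon_context = e$exon_context[1],
               n_animals = length(unique(e$animal_id)),
               carriers = paste(sort(unique(stats::na.omit(e$allele))),
                                collapse = ","),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$start, tab$end), , drop = FALSE]
  rownames(tab) <- NULL
  list(recurrent = tab[tab$n_animals >= min_animals, , drop = FALSE],
       artifacts = tab[tab$n_animals < min_animals, , drop = FALSE])
}

#' Assign a transcript to a genomic paralogue
#'
#' The transcript goes to the genomic gene with the highest gap-excluded
#' alignment identity, provided that identity clears `min_identity` and
#' beats the runner-up by `margin`; two genes within the margin yield an
#' explicit ambiguous report, and a transcript below threshold against all
#' genes founds a new gene label (next free number).
#'
#' @param transcript transcript CDS.
#' @param genomic_cds named character vector of genomic gene CDS (names
#'   like `"F1"`..`"F5"`).
#' @param min_identity assignment threshold (default 0.98).
#' @param margin required lead over the runner-up (default 0.01).
#' @return list with `gene`, `status` (`assigned`/`ambiguous`/`new_gene`),
#'   `identity`, `runner_up`, `runner_up_identity`.
#' @export
assign_gene <- function(transcript, genomic_cds, min_identity = 0.98,
                        margin = 0.01) {
  if (!length(genomic_cds)) stop("genomic CDS set is empty")
  ids <- vapply(genomic_cds, function(g) {
    pa <- Biostrings::pairwiseAlignment(
      transcript, g, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 1)
    Biostrings::nmatch(pa) /
      (Biostrings::nmatch(pa) + Biostrings::nmismatch(pa))
  }, 0)
  ord <- order(ids, decreasing = TRUE)
  best <- ids[ord[1]]
  second <- if (length(ids) > 1) ids[ord[2]] else -Inf
  if (best < min_identity) {
    nums <- suppressWarnings(as.integer(sub("^F", "", names(genomic_cds))))
    new_gene <- paste0("F", max(nums, 0L, na.rm = TRUE) + 1L)
    return(list(gene = new_gene, status = "new_gene", identity = best,
                runner_up = names(ids)[ord[2]] %||% NA_character_,
                runner_up_identity = unname(second)))
  }
  if (is.finite(second) && best - second < margin)
    return(list(gene = NA_character_, status = "ambiguous",
                identity = unname(best), runner_up = names(ids)[ord[2]],
                runner_up_identity = unname(second)))
  list(gene = names(ids)[ord[1]], status = "assigned",
       identity = unname(best), runner_up = names(ids)[ord[2]] %||% NA_character_,
       runner_up_identity = unname(second))
}
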