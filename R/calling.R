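#' @name calling
#' @title Allele calling from barcoded replicate amplicon reads
#'
#' @description
#' The calling chain mirrors long-amplicon MHC genotyping practice:
#' demultiplex on 16-nt sample barcodes, trim the amplification primers
#' (IUPAC-degenerate motifs, strand-normalized), map reads to a library of
#' known alleles, cluster the unused reads de novo into candidate novel
#' alleles, and keep only candidates confirmed in at least two independent
#' PCR replicates, with single-breakpoint PCR-chimera rejection against the
#' confirmed calls.
NULL

# pairwise Hamming separation of the manifest barcodes
barcode_separation <- function(barcodes) {
  if (length(barcodes) < 2) return(Inf)
  min(apply(combn(length(barcodes), 2), 2,
            function(ij) hamming(barcodes[ij[1]], barcodes[ij[2]])))
}

#' Demultiplex reads on sample barcodes
#'
#' A read is assigned to the unique nearest barcode (either orientation)
#' within `max_mismatch`; ties and distant reads go to the unassigned bin.
#' The manifest must keep barcodes mutually >= 2*max_mismatch + 1 apart so
#' that assignment is unambiguous by construction.
#'
#' @param reads data frame with columns `read_id`, `sequence` (and
#'   optionally `replicate`).
#' @param manifest data frame with columns `barcode`, `animal_id`.
#' @param max_mismatch maximum barcode mismatches (default 1).
#' @return the `reads` data frame with an `animal_id` column (`NA` =
#'   unassigned).
#' @export
demultiplex <- function(reads, manifest, max_mismatch = 1) {
  need_cols(reads, c("read_id", "sequence"), "reads")
  need_cols(manifest, c("barcode", "animal_id"), "manifest")
  bl <- unique(nchar(manifest$barcode))
  if (length(bl) != 1) stop("manifest barcodes must share one length")
  if (barcode_separation(manifest$barcode) < 2 * max_mismatch + 1)
    stop("manifest rejected: barcodes closer than 2*max_mismatch + 1")
  pre_f <- substr(reads$sequence, 1, bl)
  pre_r <- substr(revcomp(reads$sequence), 1, bl)
  mf <- seq_matrix(pre_f)
  mr <- seq_matrix(pre_r)
  dist_to <- function(m, bc) {
    b <- strsplit(bc, "")[[1]]
    rowSums(m != matrix(b, nrow(m), bl, byrow = TRUE))
  }
  d <- vapply(manifest$barcode, function(bc)
    pmin(dist_to(mf, bc), dist_to(mr, bc)), numeric(nrow(reads)))
  d <- matrix(d, nrow = nrow(reads))
  best <- apply(d, 1, min)
  n_best <- rowSums(d == best)
  hit <- max.col(-d, ties.method = "first")
  assigned <- best <= max_mismatch & n_best == 1
  reads$animal_id <- ifelse(assigned, manifest$animal_id[hit], NA_character_)
  reads
}

# scan a motif (IUPAC degeneracy allowed) over candidate start positions in
# an equal-length read matrix; returns best position and mismatch count
motif_scan <- function(mat, motif, starts) {
  mchars <- strsplit(motif, "")[[1]]
  allowed <- IUPAC_SETS[mchars]
  n <- nrow(mat)
  best_mm <- rep(Inf, n)
  best_at <- rep(NA_integer_, n)
  for (s in starts) {
    if (s < 1 || s + length(mchars) - 1 > ncol(mat)) next
    mm <- integer(n)
    for (j in seq_along(mchars))
      mm <- mm + !(mat[, s + j - 1] %in% allowed[[j]])
    upd <- mm < best_mm
    best_mm[upd] <- mm[upd]
    best_at[upd] <- s
  }
  list(pos = best_at, mism = best_mm)
}

#' Trim amplification primers and normalize orientation
#'
#' Locates the forward motif near the 5' end and the reverse complement of
#' the reverse motif near the 3' end (each within `max_mismatch`, IUPAC
#' degeneracy in the motif respected), in either read orientation, and
#' returns the excised insert on the forward strand. Reads missing either
#' motif are untrimmable (`NA`) and excluded from calling.
#'
#' @param seqs character vector of read sequences.
#' @param fwd,rev primer motifs (5'->3' as ordered for PCR).
#' @param max_mismatch per-motif mismatch allowance (default 2).
#' @param lead maximum offset of the forward motif from the read start
#'   (default 40, room for a 16-nt barcode plus slack).
#' @return data frame with columns `trimmed` (NA if untrimmable) and
#'   `orientation` (`"fwd"`, `"rev"` or NA).
#' @export
trim_primers <- function(seqs, fwd, rev, max_mismatch = 2, lead = 40) {
  stopifnot(nchar(fwd) > 0, nchar(rev) > 0)
  out_seq <- rep(NA_character_, length(seqs))
  out_ori <- rep(NA_character_, length(seqs))
  rc_rev <- revcomp(rev)
  lf <- nchar(fwd); lr <- nchar(rc_rev)
  for (len in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == len)
    if (len < lf + lr + 1) next
    for (ori in c("fwd", "rev")) {
      open <- idx[is.na(out_seq[idx])]
      if (!length(open)) break
      s <- if (ori == "fwd") seqs[open] else revcomp(seqs[open])
      mat <- seq_matrix(s)
      f <- motif_scan(mat, fwd, 1:min(lead, len - lf))
      r <- motif_scan(mat, rc_rev, max(1, len - lr - lead + 1):(len - lr + 1))
      ok <- f$mism <= max_mismatch & r$mism <= max_mismatch &
        !is.na(f$pos) & !is.na(r$pos) & (f$pos + lf) <= (r$pos - 1)
      if (any(ok)) {
        out_seq[open[ok]] <- substr(s[ok], f$pos[ok] + lf, r$pos[ok] - 1)
        out_ori[open[ok]] <- ori
      }
    }
  }
  data.frame(trimmed = out_seq, orientation = out_ori,
             stringsAsFactors = FALSE)
}

# identity of same-length strings vs a target (vectorized)
identity_to <- function(mat, target) {
  t <- strsplit(target, "")[[1]]
  1 - rowSums(mat != matrix(t, nrow(mat), ncol(mat), byrow = TRUE)) / ncol(mat)
}

#' Map trimmed reads to a known-allele library
#'
#' A read is assigned to a library allele iff the global-alignment identity
#' is at least `min_identity` and that allele is the unique best hit;
#' otherwise the read is left unused (input to de novo calling). An empty
#' library leaves every read unused.
#'
#' @param trimmed character vector of trimmed read sequences.
#' @param library named character vector of known allele sequences
#'   (non-redundant).
#' @param min_identity minimum full-length identity (default 0.98).
#' @return list with `allele` (per-read assigned allele name or NA),
#'   `identity` (best identity), `unused` (indices of unused reads).
#' @export
map_to_library <- function(trimmed, library, min_identity = 0.98) {
  n <- length(trimmed)
  allele <- rep(NA_character_, n)
  ident <- rep(NA_real_, n)
  if (length(library) == 0)
    return(list(allele = allele, identity = ident, unused = seq_len(n)))
  if (anyDuplicated(library))
    stop("library must be non-redundant (duplicate sequences present)")
  if (is.null(names(library)))
    names(library) <- paste0("lib", seq_along(library))
  for (len in unique(nchar(trimmed))) {
    idx <- which(nchar(trimmed) == len)
    mat <- seq_matrix(trimmed[idx])
    idm <- vapply(library, function(al) {
      if (nchar(al) == len) identity_to(mat, al)
      else if (abs(nchar(al) - len) > 0.1 * len) rep(0, length(idx))
      else vapply(trimmed[idx], function(rd) {
        pa <- Biostrings::pairwiseAlignment(rd, al, type = "global",
                                            gapOpening = 5, gapExtension = 1)
        Biostrings::nmatch(pa) / max(nchar(rd), nchar(al))
      }, 0)
    }, numeric(length(idx)))
    idm <- matrix(idm, nrow = length(idx))
    best <- apply(idm, 1, max)
    n_best <- rowSums(idm == best)
    hit <- max.col(idm, ties.method = "first")
    take <- best >= min_identity & n_best == 1
    allele[idx[take]] <- names(library)[hit[take]]
    ident[idx] <- best
  }
  list(allele = allele, identity = ident, unused = which(is.na(allele)))
}

# column-majority consensus of an equal-length read matrix; ties broken by
# lexicographic base order (deterministic)
column_consensus <- function(mat) {
  counts <- vapply(BASES, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  paste(BASES[max.col(counts, ties.method = "first")], collapse = "")
}

#' De novo candidate alleles from unused reads
#'
#' Reads are grouped by length, clustered greedily by identity (radius on
#' substitution distance), and each cluster is phased on its polymorphic
#' columns (minor-base frequency above `polymorphic_minor`): reads sharing a
#' haplotype pattern form a candidate whose sequence is the column-majority
#' consensus. Patterns below `min_cluster_size` reads (sporadic errors, PCR
#' chimeras with random breakpoints) are reassigned to the nearest core
#' pattern or discarded as noise.
#'
#' @param seqs character vector of trimmed unused reads from one animal and
#'   one replicate.
#' @param min_cluster_size minimum reads supporting a candidate (default 5).
#' @param cluster_radius substitution-distance radius (fraction of length)
#'   for the coarse paralogue-level clustering (default 0.03).
#' @param polymorphic_minor minor-base frequency above which a column is
#'   treated as allelic rather than error (default 0.25).
#' @return data frame: `sequence`, `support` (reads), one row per candidate.
#' @export
denovo_call <- function(seqs, min_cluster_size = 5, cluster_radius = 0.03,
                        polymorphic_minor = 0.25) {
  cand <- list()
  for (len in unique(nchar(seqs))) {
    pool <- seqs[nchar(seqs) == len]
    radius <- ceiling(cluster_radius * len)
    while (length(pool) >= min_cluster_size) {
      mat <- seq_matrix(pool)
      d <- (1 - identity_to(mat, pool[1])) * len
      grp <- d <= radius
      if (sum(grp) < min_cluster_size) {    # seed is noise/chimera
        pool <- pool[-1]
        next
      }
      gm <- mat[grp, , drop = FALSE]
      pool <- pool[!grp]
      # phase on polymorphic columns
      nn <- nrow(gm)
      counts <- vapply(BASES, function(b) colSums(gm == b), numeric(ncol(gm)))
      minor <- 1 - apply(counts, 1, max) / nn
      poly <- which(minor >= polymorphic_minor)
      if (!length(poly)) {
        cand[[length(cand) + 1]] <- data.frame(
          sequence = column_consensus(gm), support = nn,
          stringsAsFactors = FALSE)
        next
      }
      pat <- apply(gm[, poly, drop = FALSE], 1, paste, collapse = "")
      tab <- sort(table(pat), decreasing = TRUE)
      cores <- names(tab)[tab >= min_cluster_size]
      if (!length(cores)) next
      assign <- match(pat, cores)
      stray <- which(is.na(assign))
      if (length(stray) && length(cores)) {
        core_mat <- do.call(rbind, strsplit(cores, ""))
        for (i in stray) {
          p <- strsplit(pat[i], "")[[1]]
          dd <- rowSums(core_mat != matrix(p, nrow(core_mat),
                                           length(p), byrow = TRUE))
          if (sum(dd == min(dd)) == 1) assign[i] <- which.min(dd)
        }
      }
      for (k in seq_along(cores)) {
        rows <- which(assign == k)
        if (length(rows) < min_cluster_size) next
        cand[[length(cand) + 1]] <- data.frame(
          sequence = column_consensus(gm[rows, , drop = FALSE]),
          support = length(rows), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand))
    return(data.frame(sequence = character(0), support = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, cand)
  # merge identical candidates (e.g. one allele recovered from two clusters)
  agg <- tapply(out$support, out$sequence, sum)
  data.frame(sequence = names(agg), support = as.integer(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

# is `cand` a single-breakpoint mosaic of x (5') and y (3')?
is_mosaic_of <- function(cand, x, y) {
  if (nchar(cand) != nchar(x) || nchar(cand) != nchar(y)) return(FALSE)
  if (cand == x || cand == y) return(FALSE)
  rc <- charToRaw(cand)
  mx <- which(rc != charToRaw(x))
  my <- which(rc != charToRaw(y))
  if (!length(mx) || !length(my)) return(FALSE)
  max(my) < min(mx)          # exists k: cand==x on [1..k], ==y on (k..L]
}

#' Confirm candidate alleles across independent PCR replicates
#'
#' Identical candidates recovered in at least `min_replicates` replicates
#' become confirmed; single-replicate candidates stay provisional; any
#' candidate explainable as a single-breakpoint two-allele mosaic of other
#' confirmed calls is demoted to a rejected PCR-chimera artifact.
#'
#' @param candidates data frame with columns `replicate`, `sequence`,
#'   `support` (one animal).
#' @param known optional character vector of sequences already matched to
#'   the known-allele library for this animal (treated as confirmed for the
#'   mosaic test).
#' @param min_replicates replicates required for confirmation (default 2).
#' @return data frame: `sequence`, `status` (`confirmed_novel`,
#'   `provisional`, `rejected_artifact`), `supporting_replicates`,
#'   `read_support`.
#' @export
confirm_alleles <- function(candidates, known = character(0),
                            min_replicates = 2) {
  if (nrow(candidates) == 0)
    return(data.frame(sequence = character(0), status = character(0),
                      supporting_replicates = integer(0),
                      read_support = integer(0), stringsAsFactors = FALSE))
  reps <- tapply(candidates$replicate, candidates$sequence,
                 function(x) length(unique(x)))
  supp <- tapply(candidates$support, candidates$sequence, sum)
  out <- data.frame(sequence = names(reps),
                    status = ifelse(reps >= min_replicates,
                                    "confirmed_novel", "provisional"),
                    supporting_replicates = as.integer(reps),
                    read_support = as.integer(supp),
                    row.names = NULL, stringsAsFactors = FALSE)
  confirmed <- c(out$sequence[out$status == "confirmed_novel"], known)
  if (length(confirmed) >= 2) {
    for (i in which(out$status == "confirmed_novel")) {
      others <- setdiff(confirmed, out$sequence[i])
      if (length(others) < 2) next
      pairs <- combn(others, 2)
      for (k in seq_len(ncol(pairs))) {
        x <- pairs[1, k]; y <- pairs[2, k]
        if (is_mosaic_of(out$sequence[i], x, y) ||
            is_mosaic_of(out$sequence[i], y, x)) {
          out$status[i] <- "rejected_artifact"
          break
        }
      }
    }
  }
  out
}

#' Call alleles for every animal from raw barcoded reads
#'
#' Runs the full calling chain (demultiplex, trim, map, de novo, confirm).
#' The two-independent-PCR rule is applied uniformly: known-library matches
#' and novel candidates alike need support in `min_replicates` replicates.
#'
#' @param reads data frame (`read_id`, `replicate`, `sequence`).
#' @param manifest barcode manifest (`barcode`, `animal_id`).
#' @param primers list with `fwd` and `rev` motifs.
#' @param library named character vector of known alleles (may be empty).
#' @param min_identity mapping identity threshold (default 0.98).
#' @param min_cluster_size de novo cluster support threshold (default 5).
#' @param max_barcode_mismatch demultiplexing mismatch allowance (default 1).
#' @param min_replicates confirmation rule (default 2).
#' @return object of class `mhcf_calls`: data frame with `animal_id`,
#'   `sequence`, `allele` (library name or NA), `status` (`known_match`,
#'   `confirmed_novel`, `provisional`, `rejected_artifact`),
#'   `supporting_replicates`, `read_support`.
#' @export
call_alleles <- function(reads, manifest, primers, library = character(0),
                         min_identity = 0.98, min_cluster_size = 5,
                         max_barcode_mismatch = 1, min_replicates = 2) {
  dm <- demultiplex(reads, manifest, max_mismatch = max_barcode_mismatch)
  dm <- dm[!is.na(dm$animal_id), , drop = FALSE]
  res <- list()
  for (a in unique(manifest$animal_id)) {
    sub <- dm[dm$animal_id == a, , drop = FALSE]
    if (!nrow(sub)) next
    # discovery always runs de novo on all trimmed reads: at F-gene
    # divergences (alleles separated by scattered point mutations) a read of
    # a still-unknown allele can sit within sequencing-error distance of a
    # known allele, so the mapped/unused split alone cannot be trusted to
    # isolate novelty.  Mapping supplies per-replicate read support and the
    # known/novel label of each consensus candidate.
    known_hits <- list()
    novo <- list()
    for (r in sort(unique(sub$replicate))) {
      rr <- sub[sub$replicate == r, , drop = FALSE]
      tr <- trim_primers(rr$sequence, primers$fwd, primers$rev)
      good <- tr$trimmed[!is.na(tr$trimmed)]
      if (!length(good)) next
      mp <- map_to_library(good, library, min_identity = min_identity)
      dn <- denovo_call(good, min_cluster_size = min_cluster_size)
      if (!nrow(dn)) next
      is_known <- dn$sequence %in% library
      if (any(is_known)) {
        kn <- dn[is_known, , drop = FALSE]
        kn$allele <- names(library)[match(kn$sequence, library)]
        # read support from mapping where available, else cluster size
        mapped <- table(mp$allele[!is.na(mp$allele)])
        kn$support <- ifelse(kn$allele %in% names(mapped),
                             as.integer(mapped[kn$allele]), kn$support)
        known_hits[[length(known_hits) + 1]] <- cbind(replicate = r, kn)
      }
      if (any(!is_known))
        novo[[length(novo) + 1]] <-
          cbind(replicate = r, dn[!is_known, , drop = FALSE])
    }
    kh <- if (length(known_hits)) do.call(rbind, known_hits) else
      data.frame(replicate = integer(0), allele = character(0),
                 support = integer(0), sequence = character(0))
    known_call <- if (nrow(kh)) {
      reps <- tapply(kh$replicate, kh$allele, function(x) length(unique(x)))
      supp <- tapply(kh$support, kh$allele, sum)
      keep <- reps >= min_replicates
      data.frame(animal_id = a,
                 sequence = unname(library[names(reps)[keep]]),
                 allele = names(reps)[keep], status = "known_match",
                 supporting_replicates = as.integer(reps[keep]),
                 read_support = as.integer(supp[keep]),
                 stringsAsFactors = FALSE)
    } else NULL
    nv <- if (length(novo)) do.call(rbind, novo) else
      data.frame(replicate = integer(0), sequence = character(0),
                 support = integer(0))
    conf <- confirm_alleles(nv, known = known_call$sequence %||% character(0),
                            min_replicates = min_replicates)
    novel_call <- if (nrow(conf)) cbind(
      data.frame(animal_id = a, stringsAsFactors = FALSE),
      sequence = conf$sequence, allele = NA_character_,
      status = conf$status,
      supporting_replicates = conf$supporting_replicates,
      read_support = conf$read_support) else NULL
    res[[length(res) + 1]] <- rbind(known_call, novel_call)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("mhcf_calls", class(out))
  out
}
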