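# Consensus calling across cloned amplifications. Conflicts are always
# resolved conservatively: a tie or an inter-replicate disagreement becomes
# the IUPAC code of the observed bases, never an arbitrary pick, so damage-
# derived uncertainty stays visible in the final sequence (e.g. unresolved
# A/G positions carried as R).

#' Construct an amplicon (one cloned PCR product)
#'
#' @param sample_id,fragment_id,pcr_session Identifiers.
#' @param clones Character vector of equal-length, aligned, primer-trimmed
#'   clone sequences over A/C/G/T. Gapped or non-nucleotide clones are
#'   rejected; realignment is out of scope.
#' @param coords Length-2 integer vector, 1-based inclusive start/end on the
#'   gene reference; the clone length must equal `end - start + 1`.
#' @return An object of class `amplicon`.
#' @export
amplicon <- function(sample_id, fragment_id, pcr_session, clones, coords) {
  if (length(clones) < 1L) stop("an amplicon needs at least one clone")
  clones <- toupper(clones)
  n <- nchar(clones)
  if (length(unique(n)) != 1L) stop("clones have unequal lengths")
  coords <- as.integer(coords)
  if (length(coords) != 2L || coords[2L] < coords[1L]) {
    stop("coords must be (start, end) with end >= start")
  }
  if (n[1L] != coords[2L] - coords[1L] + 1L) {
    stop("clone length does not match coords span")
  }
  if (any(grepl("[^ACGT]", clones))) {
    stop("clones must contain only A/C/G/T (no gaps or ambiguity codes)")
  }
  structure(list(sample_id = sample_id, fragment_id = fragment_id,
                 pcr_session = pcr_session, clones = clones,
                 coords = coords),
            class = "amplicon")
}

#' Group a simulated library into amplicons
#'
#' One amplicon per sample x fragment x PCR session with at least one clone.
#'
#' @param lib A `clone_library`.
#' @return List of [amplicon()] objects.
#' @export
amplicons_from_library <- function(lib) {
  stopifnot(inherits(lib, "clone_library"))
  cl <- lib$clones
  if (!nrow(cl)) return(list())
  key <- interaction(cl$sample_id, cl$fragment_id, cl$pcr_session,
                     drop = TRUE)
  out <- lapply(split(cl, key), function(d) {
    amplicon(d$sample_id[1L], d$fragment_id[1L], d$pcr_session[1L],
             d$seq, c(d$start[1L], d$end[1L]))
  })
  unname(out)
}

.empty_amb <- function() {
  data.frame(position = integer(), code = character(),
             stringsAsFactors = FALSE)
}

new_consensus_record <- function(sequence, level, coords,
                                 sample_id = NA_character_,
                                 fragment_id = NA_character_,
                                 pcr_session = NA_character_,
                                 support = NULL,
                                 replication_status = NA_character_,
                                 ambiguous_positions = .empty_amb(),
                                 contigs = NULL, uncovered = NULL,
                                 n_clones = NA_integer_) {
  coords <- as.integer(coords)
  if (is.null(contigs)) {
    contigs <- data.frame(start = coords[1L], end = coords[2L],
                          sequence = sequence, stringsAsFactors = FALSE)
  }
  if (is.null(uncovered)) {
    uncovered <- data.frame(start = integer(), end = integer())
  }
  stopifnot(all(nchar(contigs$sequence) == contigs$end - contigs$start + 1L))
  structure(list(sequence = sequence, level = level,
                 coords = as.integer(coords), sample_id = sample_id,
                 fragment_id = fragment_id, pcr_session = pcr_session,
                 support = support, replication_status = replication_status,
                 ambiguous_positions = ambiguous_positions,
                 contigs = contigs, uncovered = uncovered,
                 n_clones = n_clones),
            class = "consensus_record")
}

#' @export
print.consensus_record <- function(x, ...) {
  cat(sprintf("<consensus_record level=%s span=%d-%d contigs=%d>\n",
              x$level, x$coords[1L], x$coords[2L], nrow(x$contigs)))
  if (nrow(x$ambiguous_positions)) {
    cat("  ambiguous: ",
        paste(sprintf("%s%d", x$ambiguous_positions$code,
                      x$ambiguous_positions$position), collapse = ", "),
        "\n", sep = "")
  }
  if (!is.na(x$replication_status)) {
    cat("  replication:", x$replication_status, "\n")
  }
  invisible(x)
}

# per-position IUPAC bit sets of a record, over its covered positions
.record_sets <- function(rec) {
  pos <- integer(0); bits <- integer(0)
  for (i in seq_len(nrow(rec$contigs))) {
    p <- rec$contigs$start[i]:rec$contigs$end[i]
    b <- .iupac_bits(.char_split(rec$contigs$sequence[i]))
    pos <- c(pos, p); bits <- c(bits, b)
  }
  list(pos = pos, bits = bits)
}

#' Call the consensus of one amplicon
#'
#' Strict per-column plurality over the clones; a column whose top count is
#' tied between bases yields the IUPAC code of the tied set. Per-column base
#' counts are recorded as support so every call is auditable.
#'
#' @param a An [amplicon()].
#' @return A `consensus_record` (level `"amplicon"`) with a `support` matrix
#'   (positions x 4 base counts) and `ambiguous_positions` listing tie
#'   columns in gene coordinates.
#' @export
call_amplicon_consensus <- function(a) {
  stopifnot(inherits(a, "amplicon"))
  m <- do.call(rbind, strsplit(a$clones, "", fixed = TRUE))
  L <- ncol(m)
  support <- matrix(0L, nrow = L, ncol = 4L,
                    dimnames = list(NULL, .BASES))
  seq_out <- character(L)
  amb <- .empty_amb()
  for (j in seq_len(L)) {
    cnt <- tabulate(factor(m[, j], levels = .BASES), nbins = 4L)
    support[j, ] <- cnt
    top <- which(cnt == max(cnt))
    if (length(top) == 1L) {
      seq_out[j] <- .BASES[top]
    } else {
      code <- set_to_iupac(.BASES[top])
      seq_out[j] <- code
      amb <- rbind(amb, data.frame(position = a$coords[1L] + j - 1L,
                                   code = code, stringsAsFactors = FALSE))
    }
  }
  new_consensus_record(paste(seq_out, collapse = ""), "amplicon", a$coords,
                       sample_id = a$sample_id, fragment_id = a$fragment_id,
                       pcr_session = a$pcr_session, support = support,
                       ambiguous_positions = amb,
                       n_clones = length(a$clones))
}

.span_overlap_frac <- function(c1, c2) {
  ov <- min(c1[2L], c2[2L]) - max(c1[1L], c2[1L]) + 1L
  if (ov <= 0L) return(0)
  ov / min(c1[2L] - c1[1L] + 1L, c2[2L] - c2[1L] + 1L)
}

#' Classify the replication status of a fragment's amplicons
#'
#' Ranks the evidence that a fragment's sequence was independently
#' replicated: two or more amplicons from distinct PCR sessions are full
#' independent replicates; amplicons from a single session replicate only
#' within-session; exactly two amplicons with distinct coordinate spans
#' overlapping by at least half the shorter span count as valid overlapping
#' replicates; a single amplicon whose consensus is IUPAC-compatible over the
#' shared span with another sample's validated consensus is cross-validated;
#' anything else is unvalidated.
#'
#' @param fragment_id Fragment (region) identifier, for reporting.
#' @param amplicons List of [amplicon()]s from one sample and fragment
#'   region.
#' @param cross_sample_consensuses Optional list of validated
#'   `consensus_record`s from other samples, used only for the
#'   single-amplicon case.
#' @return One of `"replicated_independent"`, `"replicated_same_session"`,
#'   `"overlapping_replicates"`, `"single_cross_validated"`,
#'   `"unvalidated"`.
#' @export
validate_replication <- function(fragment_id, amplicons,
                                 cross_sample_consensuses = list()) {
  if (length(amplicons) == 0L) stop("no amplicons for ", fragment_id)
  if (length(amplicons) >= 2L) {
    spans <- vapply(amplicons, function(a) paste(a$coords, collapse = "-"),
                    "")
    sessions <- vapply(amplicons, function(a) a$pcr_session, "")
    if (length(unique(spans)) > 1L) {
      if (length(amplicons) == 2L &&
          .span_overlap_frac(amplicons[[1L]]$coords,
                             amplicons[[2L]]$coords) >= 0.5) {
        return("overlapping_replicates")
      }
    }
    if (length(unique(sessions)) >= 2L) return("replicated_independent")
    return("replicated_same_session")
  }
  # single amplicon: try cross-sample validation
  cons <- call_amplicon_consensus(amplicons[[1L]])
  for (other in cross_sample_consensuses) {
    if (.iupac_identical_over_shared(cons, other)) {
      return("single_cross_validated")
    }
  }
  "unvalidated"
}

.iupac_identical_over_shared <- function(rec1, rec2) {
  s1 <- .record_sets(rec1); s2 <- .record_sets(rec2)
  shared <- intersect(s1$pos, s2$pos)
  if (!length(shared)) return(FALSE)
  b1 <- s1$bits[match(shared, s1$pos)]
  b2 <- s2$bits[match(shared, s2$pos)]
  all(bitwAnd(b1, b2) > 0L)
}

#' Merge replicate consensuses of one fragment
#'
#' Positions where the replicates agree keep their base; positions where two
#' replicates disagree (e.g. A versus G) become the IUPAC code of the
#' observed pair and are reported; a three-way conflict yields the three-fold
#' code with a warning. Replicates may cover different spans (overlapping
#' replicates); positions covered by a single replicate are copied through.
#'
#' @param consensuses List of `consensus_record`s of one sample/fragment
#'   region, coordinate-registered.
#' @param replication_status Optional status to store on the result.
#' @return A `consensus_record` (level `"fragment"`) whose
#'   `ambiguous_positions` lists every inter-replicate conflict.
#' @export
merge_replicates <- function(consensuses, replication_status = NA_character_) {
  stopifnot(length(consensuses) >= 1L)
  if (length(consensuses) == 1L) {
    rec <- consensuses[[1L]]
    out <- new_consensus_record(rec$sequence, "fragment", rec$coords,
                                sample_id = rec$sample_id,
                                fragment_id = rec$fragment_id,
                                ambiguous_positions = rec$ambiguous_positions,
                                replication_status = replication_status,
                                n_clones = rec$n_clones)
    return(out)
  }
  sets <- lapply(consensuses, .record_sets)
  all_pos <- sort(unique(unlist(lapply(sets, `[[`, "pos"))))
  if (!all(diff(all_pos) == 1L)) {
    stop("replicates do not cover a contiguous span")
  }
  out_bits <- integer(length(all_pos))
  conflict <- logical(length(all_pos))
  for (i in seq_along(all_pos)) {
    p <- all_pos[i]
    covering <- unlist(lapply(sets, function(s) s$bits[match(p, s$pos)]))
    covering <- covering[!is.na(covering)]
    if (length(unique(covering)) == 1L) {
      out_bits[i] <- covering[1L]
    } else {
      out_bits[i] <- Reduce(bitwOr, covering)
      conflict[i] <- TRUE
    }
  }
  codes <- .BITS_CODE[out_bits]
  n_fold <- vapply(out_bits[conflict],
                   function(b) sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L), 0L)
  if (any(n_fold >= 3L)) {
    warning("three-way conflict at position(s) ",
            paste(all_pos[conflict][n_fold >= 3L], collapse = ", "))
  }
  amb <- data.frame(position = all_pos[conflict],
                    code = codes[conflict], stringsAsFactors = FALSE)
  first <- consensuses[[1L]]
  new_consensus_record(paste(codes, collapse = ""), "fragment",
                       c(min(all_pos), max(all_pos)),
                       sample_id = first$sample_id,
                       fragment_id = first$fragment_id,
                       replication_status = replication_status,
                       ambiguous_positions = amb,
                       n_clones = sum(vapply(consensuses,
                                             function(x) {
                                               if (is.na(x$n_clones)) 0L
                                               else x$n_clones
                                             }, 0L)))
}

#' Assemble fragment consensuses into a sample consensus
#'
#' Fragments are sorted by start coordinate and merged: in overlap columns
#' the two codes must be IUPAC-compatible (non-empty base-set intersection)
#' and the intersection code is emitted; an incompatible overlap (e.g. A
#' versus C) is a hard error naming the fragment pair and position. Gaps in
#' coverage split the output into contigs, with uncovered spans reported.
#'
#' @param fragment_consensuses List of `consensus_record`s with coordinates.
#' @param sample_id Optional identifier for the result.
#' @return A `consensus_record` (level `"sample"`) with `contigs` and
#'   `uncovered` tables.
#' @export
assemble_fragments <- function(fragment_consensuses, sample_id = NA_character_) {
  stopifnot(length(fragment_consensuses) >= 1L)
  units <- list()
  for (rec in fragment_consensuses) {
    for (i in seq_len(nrow(rec$contigs))) {
      units[[length(units) + 1L]] <- list(
        start = rec$contigs$start[i], end = rec$contigs$end[i],
        bits = .iupac_bits(.char_split(rec$contigs$sequence[i])),
        id = if (is.na(rec$fragment_id)) "contig" else rec$fragment_id)
    }
  }
  units <- units[order(vapply(units, `[[`, 0L, "start"),
                       vapply(units, `[[`, 0L, "end"))]
  contigs <- list()
  cur <- units[[1L]]
  for (u in units[-1L]) {
    if (u$start <= cur$end + 1L) {
      # overlap columns: intersect
      if (u$start <= cur$end) {
        ov <- u$start:min(cur$end, u$end)
        cur_idx <- ov - cur$start + 1L
        u_idx <- ov - u$start + 1L
        inter <- bitwAnd(cur$bits[cur_idx], u$bits[u_idx])
        if (any(inter == 0L)) {
          bad <- ov[which(inter == 0L)[1L]]
          stop(sprintf("incompatible overlap between %s and %s at position %d",
                       cur$id, u$id, bad))
        }
        cur$bits[cur_idx] <- inter
      }
      if (u$end > cur$end) {
        cur$bits <- c(cur$bits, u$bits[(cur$end - u$start + 2L):length(u$bits)])
        cur$end <- u$end
      }
      cur$id <- paste(unique(c(cur$id, u$id)), collapse = "+")
    } else {
      contigs[[length(contigs) + 1L]] <- cur
      cur <- u
    }
  }
  contigs[[length(contigs) + 1L]] <- cur
  contig_df <- do.call(rbind, lapply(contigs, function(cg) {
    data.frame(start = cg$start, end = cg$end,
               sequence = paste(.BITS_CODE[cg$bits], collapse = ""),
               stringsAsFactors = FALSE)
  }))
  uncovered <- data.frame(start = integer(), end = integer())
  if (nrow(contig_df) > 1L) {
    uncovered <- data.frame(start = head(contig_df$end, -1L) + 1L,
                            end = contig_df$start[-1L] - 1L)
  }
  new_consensus_record(paste(contig_df$sequence, collapse = ""), "sample",
                       c(min(contig_df$start), max(contig_df$end)),
                       sample_id = sample_id, contigs = contig_df,
                       uncovered = uncovered)
}

#' Combine per-sample consensuses into the final consensus
#'
#' Per position over the union of coverage: if all covering samples are
#' IUPAC-compatible, the intersection code is emitted (so an R in one sample
#' and an A in another give A); if they are incompatible, the union code is
#' emitted with a warning (conservative, no base is discarded).
#'
#' @param sample_consensuses List of `consensus_record`s (level `"sample"`
#'   or finer).
#' @return A `consensus_record` (level `"combined"`), `ambiguous_positions`
#'   listing inter-sample incompatibilities.
#' @export
combine_samples <- function(sample_consensuses) {
  stopifnot(length(sample_consensuses) >= 1L)
  sets <- lapply(sample_consensuses, .record_sets)
  all_pos <- sort(unique(unlist(lapply(sets, `[[`, "pos"))))
  out_bits <- integer(length(all_pos))
  conflict <- logical(length(all_pos))
  for (i in seq_along(all_pos)) {
    p <- all_pos[i]
    covering <- unlist(lapply(sets, function(s) s$bits[match(p, s$pos)]))
    covering <- covering[!is.na(covering)]
    inter <- Reduce(bitwAnd, covering)
    if (inter > 0L) {
      out_bits[i] <- inter
    } else {
      out_bits[i] <- Reduce(bitwOr, covering)
      conflict[i] <- TRUE
    }
  }
  if (any(conflict)) {
    warning("incompatible samples at position(s) ",
            paste(all_pos[conflict], collapse = ", "), "; union code emitted")
  }
  codes <- .BITS_CODE[out_bits]
  runs <- split(seq_along(all_pos), cumsum(c(1L, diff(all_pos) != 1L)))
  contig_df <- do.call(rbind, lapply(runs, function(idx) {
    data.frame(start = all_pos[idx[1L]], end = all_pos[idx[length(idx)]],
               sequence = paste(codes[idx], collapse = ""),
               stringsAsFactors = FALSE)
  }))
  rownames(contig_df) <- NULL
  uncovered <- data.frame(start = integer(), end = integer())
  if (nrow(contig_df) > 1L) {
    uncovered <- data.frame(start = head(contig_df$end, -1L) + 1L,
                            end = contig_df$start[-1L] - 1L)
  }
  amb <- data.frame(position = all_pos[conflict], code = codes[conflict],
                    stringsAsFactors = FALSE)
  new_consensus_record(paste(contig_df$sequence, collapse = ""), "combined",
                       c(min(all_pos), max(all_pos)), contigs = contig_df,
                       uncovered = uncovered, ambiguous_positions = amb)
}
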