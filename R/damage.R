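# Post-mortem damage quantification: clone-versus-consensus differences
# classified into the 12 directed substitution types. Counting rule: a
# change is one distinct (position, consensus_base -> clone_base) event per
# sample and fragment, regardless of how many clones show it; two different
# changes at the same position each count once.

.SUB_TYPES <- c("T>C", "C>T", "A>G", "G>A",            # transitions
                "C>G", "A>C", "T>A", "G>T", "A>T", "C>A", "G>C", "T>G")
.TS_TYPES <- c("T>C", "C>T", "A>G", "G>A")
.CSTAR_TYPES <- c("C>T", "G>A")

new_substitution_spectrum <- function(counts, n_clones = NA_integer_,
                                      n_pcr = NA_integer_,
                                      skipped_positions = integer()) {
  stopifnot(identical(sort(names(counts)), sort(.SUB_TYPES)),
            all(counts >= 0L))
  structure(list(counts = counts[.SUB_TYPES],
                 n_clones = n_clones, n_pcr = n_pcr,
                 skipped_positions = skipped_positions),
            class = "substitution_spectrum")
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat("<substitution_spectrum>\n")
  print(x$counts[x$counts > 0L])
  st <- spectrum_stats(x)
  cat(sprintf("  total %d | %%TS %d | %%C* %d | %%TV %d\n",
              st$total_changes, st$pct_ts, st$pct_cstar, st$pct_tv))
  invisible(x)
}

#' Classify clone-versus-consensus changes
#'
#' Compares every clone to the consensus and counts each distinct
#' (position, change) event exactly once, the deduplication rule used for
#' clone-library damage tables. Columns where the consensus itself is
#' ambiguous are excluded from counting and reported.
#'
#' @param clones Character vector of equal-length clone sequences (A/C/G/T).
#' @param consensus Consensus string of the same length (IUPAC alphabet).
#' @param n_pcr Optional number of PCRs the clones came from (metadata).
#' @return A `substitution_spectrum`: counts over the 12 directed types,
#'   clone count, and the skipped (ambiguous-consensus) positions.
#' @export
classify_changes <- function(clones, consensus, n_pcr = NA_integer_) {
  clones <- toupper(clones)
  consensus <- toupper(consensus)
  if (any(nchar(clones) != nchar(consensus))) {
    stop("clone/consensus length mismatch")
  }
  cons <- .char_split(consensus)
  skipped <- which(.is_ambiguous(cons))
  m <- do.call(rbind, strsplit(clones, "", fixed = TRUE))
  counts <- stats::setNames(integer(length(.SUB_TYPES)), .SUB_TYPES)
  usable <- setdiff(seq_along(cons), skipped)
  for (j in usable) {
    alt <- setdiff(unique(m[, j]), cons[j])
    for (b in alt) {
      ty <- paste0(cons[j], ">", b)
      counts[ty] <- counts[ty] + 1L
    }
  }
  new_substitution_spectrum(counts, n_clones = length(clones), n_pcr = n_pcr,
                            skipped_positions = skipped)
}

# integer percent, rounding half away from zero (93.75 -> 94, 87.5 -> 88)
.pct_half_away <- function(x, total) {
  if (total == 0L) return(0L)
  as.integer(floor(100 * x / total + 0.5))
}

#' Summary statistics of a substitution spectrum
#'
#' Transitions TS = T>C + C>T + A>G + G>A; deaminated cytosines
#' C* = C>T + G>A (G>A being complementary-strand deamination read on the
#' reported strand); transversions TV = the remaining eight types. Percents
#' are integer, rounded half away from zero; an empty spectrum gives zeros.
#'
#' @param s A `substitution_spectrum` (or a named count vector over the 12
#'   types).
#' @return List with `pct_ts`, `pct_cstar`, `pct_tv`, `total_changes`.
#' @export
spectrum_stats <- function(s) {
  counts <- if (inherits(s, "substitution_spectrum")) s$counts else {
    full <- stats::setNames(integer(length(.SUB_TYPES)), .SUB_TYPES)
    full[names(s)] <- as.integer(s)
    full
  }
  ts <- sum(counts[.TS_TYPES])
  cstar <- sum(counts[.CSTAR_TYPES])
  total <- sum(counts)
  tv <- total - ts
  list(pct_ts = .pct_half_away(ts, total),
       pct_cstar = .pct_half_away(cstar, total),
       pct_tv = .pct_half_away(tv, total),
       total_changes = as.integer(total))
}

#' Per sample-and-fragment damage report
#'
#' One row per sample x fragment with positive amplifications: fragment
#' length, PCR counts (total and independent sessions), clone count, the 12
#' directed substitution counts, and %TS / %C* / %TV. Changes are scored
#' against each amplicon's own consensus and deduplicated across all clones
#' of the sample at the same position and change.
#'
#' @param lib A `clone_library`, or a list of [amplicon()] objects.
#' @return Data frame, one row per sample x fragment.
#' @export
damage_report <- function(lib) {
  amps <- if (inherits(lib, "clone_library")) amplicons_from_library(lib)
          else lib
  header <- c("sample_id", "fragment_id", "length_bp", "n_pcr",
              "n_pcr_independent", "n_clones", .SUB_TYPES,
              "pct_ts", "pct_cstar", "pct_tv", "total_changes")
  if (!length(amps)) {
    out <- as.data.frame(stats::setNames(
      rep(list(integer(0)), length(header)), header), check.names = FALSE)
    out$sample_id <- character(0); out$fragment_id <- character(0)
    return(out)
  }
  key <- vapply(amps, function(a) paste(a$sample_id, a$fragment_id, sep = "\r"),
                "")
  rows <- lapply(split(amps, key), function(group) {
    events <- list()
    n_clones <- 0L
    sessions <- character()
    for (a in group) {
      cons <- call_amplicon_consensus(a)
      cons_chars <- .char_split(cons$sequence)
      m <- do.call(rbind, strsplit(a$clones, "", fixed = TRUE))
      usable <- which(!.is_ambiguous(cons_chars))
      for (j in usable) {
        alt <- setdiff(unique(m[, j]), cons_chars[j])
        for (b in alt) {
          events[[length(events) + 1L]] <- c(a$coords[1L] + j - 1L,
                                             cons_chars[j], b)
        }
      }
      n_clones <- n_clones + length(a$clones)
      sessions <- c(sessions, a$pcr_session)
    }
    ev <- unique(do.call(rbind, events))
    counts <- stats::setNames(integer(length(.SUB_TYPES)), .SUB_TYPES)
    if (!is.null(ev)) {
      ty <- paste0(ev[, 2L], ">", ev[, 3L])
      tt <- table(ty)
      counts[names(tt)] <- as.integer(tt)
    }
    st <- spectrum_stats(counts)
    a1 <- group[[1L]]
    cbind(data.frame(sample_id = a1$sample_id, fragment_id = a1$fragment_id,
                     length_bp = a1$coords[2L] - a1$coords[1L] + 1L,
                     n_pcr = length(group),
                     n_pcr_independent = length(unique(sessions)),
                     n_clones = n_clones, stringsAsFactors = FALSE),
          as.data.frame(as.list(counts), check.names = FALSE),
          data.frame(pct_ts = st$pct_ts, pct_cstar = st$pct_cstar,
                     pct_tv = st$pct_tv, total_changes = st$total_changes))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$fragment_id), , drop = FALSE]
}
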