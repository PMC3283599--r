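# End-to-end orchestration: simulate -> amplicon consensus -> damage report
# -> numt screen -> genuine-only assembly -> combined consensus, with a JSON
# run manifest listing every produced file and its digest. Deterministic
# given the configuration seed.

#' Build the consensus hierarchy of a screened library
#'
#' Amplicon-level consensuses are merged into per-sample fragment
#' consensuses (replication status recorded), restricted to amplicons whose
#' sequence class the numt screen judged GENUINE, assembled into per-sample
#' consensuses and combined across samples.
#'
#' @param lib A `clone_library`.
#' @param screen A `numt_screen` result for `lib` (computed when missing).
#' @return List: `amplicon` (list of records), `fragment` (per sample x
#'   fragment merged records), `sample` (per-sample assemblies),
#'   `combined` (single record or NULL when nothing is genuine).
#' @export
consensus_pipeline <- function(lib, screen = NULL) {
  stopifnot(inherits(lib, "clone_library"))
  if (is.null(screen)) screen <- numt_screen(lib)
  amps <- amplicons_from_library(lib)
  cons <- lapply(amps, call_amplicon_consensus)
  amp_ids <- vapply(amps, function(a) {
    paste(a$sample_id, a$fragment_id, a$pcr_session, sep = "|")
  }, "")
  genuine_ids <- character()
  if (nrow(screen)) {
    keep <- screen$verdict == "GENUINE"
    genuine_ids <- unlist(strsplit(screen$members[keep], ";", fixed = TRUE))
  }
  mt <- vapply(amps, function(a) !startsWith(a$fragment_id, "I"), NA)
  use <- (amp_ids %in% genuine_ids) | !mt   # nuclear amplicons are kept
  frag_recs <- list()
  sample_recs <- list()
  for (s in unique(vapply(amps, function(a) a$sample_id, ""))) {
    s_frag <- list()
    for (f in unique(vapply(amps, function(a) a$fragment_id, ""))) {
      idx <- which(use &
                   vapply(amps, function(a) a$sample_id == s &&
                            a$fragment_id == f, NA))
      if (!length(idx)) next
      status <- validate_replication(f, amps[idx])
      rec <- merge_replicates(cons[idx], replication_status = status)
      frag_recs[[paste(s, f, sep = "|")]] <- rec
      if (!startsWith(f, "I")) s_frag[[f]] <- rec
    }
    if (length(s_frag)) {
      sample_recs[[s]] <- assemble_fragments(unname(s_frag), sample_id = s)
    }
  }
  combined <- if (length(sample_recs)) {
    combine_samples(unname(sample_recs))
  } else NULL
  list(amplicon = cons, fragment = frag_recs, sample = sample_recs,
       combined = combined)
}

.write_consensus_fasta <- function(records, path) {
  ids <- names(records)
  seqs <- vapply(records, function(r) r$sequence, "")
  # IUPAC letters are legal in BStringSet; DNAStringSet also accepts them
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
}

#' Run the full authentication pipeline
#'
#' Executes simulate, consensus, damage, numt-screen and final-assembly
#' stages in order, writing each stage's outputs under `out_dir` and a JSON
#' run manifest (`manifest.json`) with the configuration snapshot, seed and
#' an md5 digest of every produced file. A stage failure halts the run,
#' after writing a manifest recording the partial state.
#'
#' @param config A [sim_config()] (its `seed` drives every stage).
#' @param out_dir Output directory.
#' @param quiet Suppress stage-boundary messages.
#' @return Invisibly, the manifest (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir, quiet = FALSE) {
  config <- validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[paleoamp] ", ...)
  manifest <- list(config = unclass(config), seed = config$seed,
                   stages = list(), files = list())
  finish <- function() {
    paths <- unlist(manifest$files)
    if (is.null(paths)) paths <- character(0)
    digests <- as.list(tools::md5sum(paths))
    names(digests) <- basename(names(digests))
    manifest$digests <- digests
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }
  stage <- function(name, fun) {
    say("stage: ", name)
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      finish()
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  lib <- stage("simdata", function() {
    lib <- simulate_clone_library(config)
    paths <- write_library(lib, file.path(out_dir, "simdata"))
    manifest$files$simdata <<- unname(paths)
    lib
  })
  cons <- stage("consensus", function() {
    amps <- amplicons_from_library(lib)
    recs <- lapply(amps, call_amplicon_consensus)
    names(recs) <- vapply(amps, function(a) {
      paste(a$sample_id, a$fragment_id, a$pcr_session, sep = "|")
    }, "")
    p <- file.path(out_dir, "amplicon_consensus.fasta")
    .write_consensus_fasta(recs, p)
    manifest$files$consensus <<- p
    recs
  })
  stage("damage", function() {
    rep <- damage_report(lib)
    p <- file.path(out_dir, "damage_report.tsv")
    .write_tsv(rep, p)
    manifest$files$damage <<- p
    rep
  })
  screen <- stage("numt_screen", function() {
    sc <- numt_screen(lib)
    p <- file.path(out_dir, "numt_verdicts.tsv")
    .write_tsv(as.data.frame(sc), p)
    manifest$files$numt_screen <<- p
    sc
  })
  stage("assembly", function() {
    cp <- consensus_pipeline(lib, screen)
    paths <- character()
    if (length(cp$sample)) {
      p <- file.path(out_dir, "sample_consensus.fasta")
      .write_consensus_fasta(cp$sample, p)
      paths <- c(paths, p)
    }
    if (!is.null(cp$combined)) {
      p <- file.path(out_dir, "combined_consensus.fasta")
      .write_consensus_fasta(list(combined = cp$combined), p)
      paths <- c(paths, p)
    }
    manifest$files$assembly <<- paths
    cp
  })
  say("done")
  invisible(finish())
}

#' Generate the bundled demonstration dataset
#'
#' A small 3-sample library over the full 19-fragment design (cytb C1-C11
#' with primed variants, IRBP I1-I4), deterministic in the seed and fast
#' enough for examples and tests.
#'
#' @param seed Root seed (default 0).
#' @return A `clone_library`.
#' @export
make_demo_fixture <- function(seed = 0L) {
  simulate_clone_library(sim_config(seed = seed))
}
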