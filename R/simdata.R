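# Synthetic ancient-DNA clone libraries. The generator reproduces the
# statistical structure the authentication stages assume: short overlapping
# amplicons, exponential length-dependent template survival that differs
# between mitochondrial and nuclear templates, clone-level C->T/G->A
# deamination damage, rare polymerase misincorporations, and occasional
# co-amplification of a divergent numt paralog. Ground truth is retained.

.MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")
.STD_STOPS <- c("TAA", "TAG", "TGA")

.stop_codons <- function(genetic_code = c("vertebrate_mito", "standard")) {
  switch(match.arg(genetic_code),
         vertebrate_mito = .MITO_STOPS,
         standard = .STD_STOPS)
}

# Mammalian cytb third-codon-position composition used when sampling the
# mitochondrial reference (A 39%, C 36%, G 3%, T 21%).
.CYTB_POS3_FREQS <- c(A = 0.39, C = 0.36, G = 0.03, T = 0.21)

#' Configuration for the ancient-amplicon simulator
#'
#' All rates are per site. Fragment survival is modelled as
#' `exp(-max(0, L - 97) / halflife)`: every template supports the shortest
#' designed amplicon (97 bp), and survival decays exponentially beyond it,
#' with a much shorter length scale for nuclear than for mitochondrial
#' templates (mt DNA is present in many more copies per cell).
#'
#' @param mt_gene_length Length of the mitochondrial reference gene in bp,
#'   divisible by 3 (default 1140, a full cytb).
#' @param nuc_gene_length Length of the nuclear reference in bp, divisible by
#'   3 and covering the nuclear fragment coordinates (default 1206).
#' @param numt_divergence Fraction of sites at which the numt paralog differs
#'   from the mt gene (default 0.12, inside the observed 5.4-20.9% range).
#' @param deamination_rate Per-site probability that a template C is read as
#'   T in a clone (and, on the complementary strand, G as A); default 0.02.
#' @param polymerase_error_rate Per-site probability of a polymerase
#'   misincorporation, uniform over the three non-template bases
#'   (default 0.001).
#' @param clones_per_pcr Clones sequenced per positive amplification
#'   (default 8).
#' @param pcr_sessions_per_fragment Independent PCR sessions attempted per
#'   fragment and sample (default 2).
#' @param mt_survival_halflife,nuc_survival_halflife Length scales (bp) of
#'   exponential template survival (defaults 180 and 90).
#' @param numt_weight Relative template abundance of the numt versus the mt
#'   copy, in `[0, 1)` (default 0.1).
#' @param fragments Data frame with columns `fragment_id`, `start`, `end`
#'   (1-based inclusive) and optionally `gene` (`"cytb"` or `"irbp"`,
#'   inferred from the id prefix when absent). Default [fragment_table()].
#' @param samples Character vector of sample identifiers (default three
#'   samples, the study's shape).
#' @param numt_stop_free Keep the numt free of in-frame stop codons, as
#'   observed for the real co-amplified paralog (default TRUE).
#' @param seed Root seed; every stream the simulator uses is derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mt_gene_length = 1140L,
                       nuc_gene_length = 1206L,
                       numt_divergence = 0.12,
                       deamination_rate = 0.02,
                       polymerase_error_rate = 0.001,
                       clones_per_pcr = 8L,
                       pcr_sessions_per_fragment = 2L,
                       mt_survival_halflife = 180,
                       nuc_survival_halflife = 90,
                       numt_weight = 0.1,
                       fragments = fragment_table(),
                       samples = c("S1", "S2", "S3"),
                       numt_stop_free = TRUE,
                       seed = 1L) {
  cfg <- list(
    mt_gene_length = as.integer(mt_gene_length),
    nuc_gene_length = as.integer(nuc_gene_length),
    numt_divergence = numt_divergence,
    deamination_rate = deamination_rate,
    polymerase_error_rate = polymerase_error_rate,
    clones_per_pcr = as.integer(clones_per_pcr),
    pcr_sessions_per_fragment = as.integer(pcr_sessions_per_fragment),
    mt_survival_halflife = mt_survival_halflife,
    nuc_survival_halflife = nuc_survival_halflife,
    numt_weight = numt_weight,
    fragments = .check_fragments(as.data.frame(fragments)),
    samples = as.character(samples),
    numt_stop_free = isTRUE(numt_stop_free),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config A `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rates <- c(config$numt_divergence, config$deamination_rate,
             config$polymerase_error_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (config$numt_weight < 0 || config$numt_weight >= 1) {
    stop("numt_weight must lie in [0, 1)")
  }
  if (config$mt_gene_length %% 3L != 0L) {
    stop("mt_gene_length must be divisible by 3")
  }
  if (config$nuc_gene_length %% 3L != 0L) {
    stop("nuc_gene_length must be divisible by 3")
  }
  if (config$clones_per_pcr < 1L || config$pcr_sessions_per_fragment < 1L) {
    stop("clones_per_pcr and pcr_sessions_per_fragment must be >= 1")
  }
  if (config$mt_survival_halflife <= 0 || config$nuc_survival_halflife <= 0) {
    stop("survival halflives must be positive")
  }
  fr <- config$fragments
  lim <- ifelse(fr$gene == "cytb", config$mt_gene_length,
                config$nuc_gene_length)
  if (any(fr$start < 1L) || any(fr$end > lim)) {
    stop("fragment coordinates outside gene length")
  }
  config
}

# derive a deterministic per-stream seed below 2^31 from the root seed
.stream_seed <- function(root, k) {
  as.integer((as.double(root %% 65536L) * 31627 + k * 7919 + 11) %% 2147483587)
}

.run_seeded <- function(seed, expr_fun) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr_fun()
}

.sample_coding <- function(n_codons, stops, pos3_freqs = NULL) {
  # sample codon-by-codon, rejecting stops
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      p12 <- sample(.BASES, 2L, replace = TRUE)
      p3 <- if (is.null(pos3_freqs)) sample(.BASES, 1L) else
        sample(.BASES, 1L, prob = pos3_freqs)
      cd <- paste0(p12[1L], p12[2L], p3)
      if (!(cd %in% stops)) break
    }
    codons[i] <- cd
  }
  .char_split(paste(codons, collapse = ""))
}

.codons_of <- function(x) {
  # x: character vector of bases, length divisible by 3
  apply(matrix(x, nrow = 3L), 2L, paste, collapse = "")
}

#' Generate reference sequences for the simulator
#'
#' Draws a stop-free mitochondrial coding sequence (vertebrate mitochondrial
#' code, frame 1, with third-position composition matching mammalian cytb), a
#' numt paralog derived from it by random substitution at exactly the
#' configured divergence, and an unrelated stop-free nuclear coding sequence
#' (standard code). By default substitutions that would create an in-frame
#' stop in the numt are resampled, matching the observation that the real
#' co-amplified numt was stop-free.
#'
#' @param config A [sim_config()].
#' @return An object of class `reference_set`: list with `mt_seq`,
#'   `numt_seq`, `nuc_seq` (strings) and `divergence` (realised mt/numt
#'   Hamming fraction).
#' @export
generate_references <- function(config) {
  config <- validate_sim_config(config)
  .run_seeded(.stream_seed(config$seed, 0L), function() {
    mt <- .sample_coding(config$mt_gene_length / 3L, .MITO_STOPS,
                         .CYTB_POS3_FREQS)
    numt <- .derive_numt(mt, config$numt_divergence, config$numt_stop_free)
    nuc <- .sample_coding(config$nuc_gene_length / 3L, .STD_STOPS)
    refs <- list(
      mt_seq = paste(mt, collapse = ""),
      numt_seq = paste(numt, collapse = ""),
      nuc_seq = paste(nuc, collapse = ""),
      divergence = mean(mt != numt)
    )
    class(refs) <- "reference_set"
    refs
  })
}

.derive_numt <- function(mt, divergence, stop_free, max_tries = 100L) {
  L <- length(mt)
  m <- round(divergence * L)
  numt <- mt
  if (m == 0L) return(numt)
  pos <- sample.int(L, m)
  numt[pos] <- vapply(mt[pos],
                      function(b) sample(setdiff(.BASES, b), 1L), "")
  if (!stop_free) return(numt)
  subbed <- logical(L); subbed[pos] <- TRUE
  for (i in seq_len(L / 3L)) {
    idx <- (3L * i - 2L):(3L * i)
    tries <- 0L
    while (paste(numt[idx], collapse = "") %in% .MITO_STOPS) {
      free <- idx[subbed[idx]]
      if (!length(free)) {
        stop("numt stop codon without substituted position; cannot repair")
      }
      j <- if (length(free) == 1L) free else sample(free, 1L)
      numt[j] <- sample(setdiff(.BASES, c(mt[j], numt[j])), 1L)
      tries <- tries + 1L
      if (tries > max_tries) stop("could not produce stop-free numt")
    }
  }
  numt
}

.survival <- function(length_bp, halflife) {
  exp(-pmax(0, length_bp - 97) / halflife)
}

#' Simulate a cloned ancient-amplicon library
#'
#' For each sample x fragment x PCR session, the template class is drawn
#' according to relative abundance (numt versus mt for mitochondrial
#' fragments), amplification succeeds with the template's length-dependent
#' survival probability, and each of `clones_per_pcr` clones independently
#' receives deamination events (C->T, and G->A for the complementary strand,
#' on the reported strand) and polymerase errors (uniform over the three
#' non-template bases). Truth labels (template class, damage and error
#' positions) are retained per clone.
#'
#' @param config A [sim_config()].
#' @param refs A `reference_set` from [generate_references()]; generated from
#'   `config` when missing.
#' @return An object of class `clone_library`: list with `clones` (one row
#'   per clone: ids, coordinates, truth labels and sequence), `attempts`
#'   (one row per PCR attempt with success flag), `config` and `refs`.
#' @export
simulate_clone_library <- function(config, refs = generate_references(config)) {
  config <- validate_sim_config(config)
  fr <- config$fragments
  ref_chars <- list(mt = .char_split(refs$mt_seq),
                    numt = .char_split(refs$numt_seq),
                    nuc = .char_split(refs$nuc_seq))
  clone_rows <- list()
  attempt_rows <- list()
  k <- 0L
  for (s in config$samples) {
    for (f in seq_len(nrow(fr))) {
      k <- k + 1L
      res <- .run_seeded(.stream_seed(config$seed, k), function() {
        .simulate_fragment(s, fr[f, ], config, ref_chars)
      })
      clone_rows[[k]] <- res$clones
      attempt_rows[[k]] <- res$attempts
    }
  }
  lib <- list(
    clones = do.call(rbind, clone_rows),
    attempts = do.call(rbind, attempt_rows),
    config = config,
    refs = refs
  )
  rownames(lib$clones) <- NULL
  rownames(lib$attempts) <- NULL
  class(lib) <- "clone_library"
  lib
}

.simulate_fragment <- function(sample_id, frag, config, ref_chars) {
  L <- frag$length
  idx <- frag$start:frag$end
  clones <- list()
  attempts <- list()
  for (p in seq_len(config$pcr_sessions_per_fragment)) {
    if (frag$gene == "cytb" && config$numt_weight > 0) {
      is_numt <- runif(1) < config$numt_weight / (1 + config$numt_weight)
      class <- if (is_numt) "numt" else "mt"
    } else {
      class <- if (frag$gene == "cytb") "mt" else "nuc"
    }
    halflife <- if (class == "mt") config$mt_survival_halflife else
      config$nuc_survival_halflife
    success <- runif(1) < .survival(L, halflife)
    attempts[[p]] <- data.frame(
      sample_id = sample_id, fragment_id = frag$fragment_id,
      gene = frag$gene, length_bp = L, pcr_session = paste0("p", p),
      template = class, success = success, stringsAsFactors = FALSE
    )
    if (!success) next
    template <- ref_chars[[class]][idx]
    for (j in seq_len(config$clones_per_pcr)) {
      cl <- .damage_clone(template, config$deamination_rate,
                          config$polymerase_error_rate)
      clones[[length(clones) + 1L]] <- data.frame(
        sample_id = sample_id, fragment_id = frag$fragment_id,
        gene = frag$gene, pcr_session = paste0("p", p),
        clone_id = sprintf("%s|%s|p%d|c%02d", sample_id, frag$fragment_id,
                           p, j),
        start = frag$start, end = frag$end, length_bp = L,
        template_truth = class,
        n_deamination = length(cl$deam),
        n_polymerase = length(cl$err),
        damage_positions = paste(frag$start - 1L + cl$deam, collapse = ","),
        error_positions = paste(frag$start - 1L + cl$err, collapse = ","),
        seq = paste(cl$seq, collapse = ""), stringsAsFactors = FALSE
      )
    }
  }
  empty_clones <- data.frame(
    sample_id = character(), fragment_id = character(), gene = character(),
    pcr_session = character(), clone_id = character(), start = integer(),
    end = integer(), length_bp = integer(), template_truth = character(),
    n_deamination = integer(), n_polymerase = integer(),
    damage_positions = character(), error_positions = character(),
    seq = character(), stringsAsFactors = FALSE
  )
  list(
    clones = if (length(clones)) do.call(rbind, clones) else empty_clones,
    attempts = do.call(rbind, attempts)
  )
}

.damage_clone <- function(template, deamination_rate, polymerase_error_rate) {
  x <- template
  # strand-symmetric deamination as read on the reported strand
  c_sites <- which(template == "C")
  g_sites <- which(template == "G")
  deam <- c(c_sites[runif(length(c_sites)) < deamination_rate],
            g_sites[runif(length(g_sites)) < deamination_rate])
  deam <- sort(deam)
  x[deam] <- ifelse(template[deam] == "C", "T", "A")
  # polymerase misincorporation, uniform over the other three bases
  err <- which(runif(length(x)) < polymerase_error_rate)
  if (length(err)) {
    x[err] <- vapply(x[err], function(b) sample(setdiff(.BASES, b), 1L), "")
  }
  list(seq = x, deam = deam, err = err)
}

#' Nuclear amplification outcome table of a simulated library
#'
#' Aggregates the library's nuclear-fragment PCR attempts into the format the
#' preservation-threshold estimator expects.
#'
#' @param lib A `clone_library`.
#' @return Data frame with columns `sample_id`, `fragment_id`, `length_bp`,
#'   `attempts`, `successes`.
#' @export
nuclear_outcomes <- function(lib) {
  stopifnot(inherits(lib, "clone_library"))
  at <- lib$attempts[lib$attempts$gene != "cytb", , drop = FALSE]
  if (!nrow(at)) {
    return(data.frame(sample_id = character(), fragment_id = character(),
                      length_bp = integer(), attempts = integer(),
                      successes = integer(), stringsAsFactors = FALSE))
  }
  key <- interaction(at$sample_id, at$fragment_id, drop = TRUE)
  out <- do.call(rbind, lapply(split(at, key), function(d) {
    data.frame(sample_id = d$sample_id[1L], fragment_id = d$fragment_id[1L],
               length_bp = d$length_bp[1L], attempts = nrow(d),
               successes = sum(d$success), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$sample_id, out$length_bp), , drop = FALSE]
}

#' @export
print.clone_library <- function(x, ...) {
  cat("Simulated ancient-DNA clone library\n")
  cat(sprintf("  %d clones from %d positive amplifications (%d attempts)\n",
              nrow(x$clones),
              sum(x$attempts$success), nrow(x$attempts)))
  if (nrow(x$clones)) {
    tt <- table(x$clones$template_truth)
    cat("  template truth: ",
        paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Write a simulated library to disk
#'
#' Writes the clone FASTA (one record per clone, id encoding
#' sample/fragment/session/clone), a metadata TSV, a truth-label TSV, the PCR
#' attempt table, the reference FASTA and the configuration as JSON. Output
#' is byte-identical across runs with the same seed.
#'
#' @param lib A `clone_library`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_library <- function(lib, out_dir) {
  stopifnot(inherits(lib, "clone_library"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cl <- lib$clones
  paths <- c(
    clones = file.path(out_dir, "clones.fasta"),
    metadata = file.path(out_dir, "metadata.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    attempts = file.path(out_dir, "attempts.tsv"),
    references = file.path(out_dir, "references.fasta"),
    config = file.path(out_dir, "config.json")
  )
  seqs <- Biostrings::DNAStringSet(if (nrow(cl)) cl$seq else character())
  names(seqs) <- cl$clone_id
  Biostrings::writeXStringSet(seqs, paths[["clones"]])
  meta_cols <- c("clone_id", "sample_id", "fragment_id", "gene",
                 "pcr_session", "start", "end", "length_bp")
  truth_cols <- c("clone_id", "template_truth", "n_deamination",
                  "n_polymerase", "damage_positions", "error_positions")
  .write_tsv(cl[, meta_cols, drop = FALSE], paths[["metadata"]])
  .write_tsv(cl[, truth_cols, drop = FALSE], paths[["truth"]])
  .write_tsv(lib$attempts, paths[["attempts"]])
  refs <- Biostrings::DNAStringSet(c(mt = lib$refs$mt_seq,
                                     numt = lib$refs$numt_seq,
                                     nuc = lib$refs$nuc_seq))
  Biostrings::writeXStringSet(refs, paths[["references"]])
  cfg <- lib$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = NA)
}

#' Read a library written by [write_library()]
#'
#' @param dir Directory produced by [write_library()].
#' @return A `clone_library` (the round trip preserves clones, attempts,
#'   references and configuration).
#' @export
read_library <- function(dir) {
  meta <- .read_tsv(file.path(dir, "metadata.tsv"))
  truth <- .read_tsv(file.path(dir, "truth.tsv"))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "clones.fasta"))
  cl <- merge(meta, truth, by = "clone_id", sort = FALSE)
  cl$seq <- as.character(fa)[cl$clone_id]
  cl$damage_positions[is.na(cl$damage_positions)] <- ""
  cl$error_positions[is.na(cl$error_positions)] <- ""
  ord <- c("sample_id", "fragment_id", "gene", "pcr_session", "clone_id",
           "start", "end", "length_bp", "template_truth", "n_deamination",
           "n_polymerase", "damage_positions", "error_positions", "seq")
  cl <- cl[, ord, drop = FALSE]
  refs_fa <- Biostrings::readDNAStringSet(file.path(dir, "references.fasta"))
  refs <- list(mt_seq = as.character(refs_fa[["mt"]]),
               numt_seq = as.character(refs_fa[["numt"]]),
               nuc_seq = as.character(refs_fa[["nuc"]]))
  refs$divergence <- p_distance(refs$mt_seq, refs$numt_seq)[[1L]]
  class(refs) <- "reference_set"
  cfg_raw <- jsonlite::read_json(file.path(dir, "config.json"),
                                 simplifyVector = TRUE)
  cfg <- sim_config(
    mt_gene_length = cfg_raw$mt_gene_length,
    nuc_gene_length = cfg_raw$nuc_gene_length,
    numt_divergence = cfg_raw$numt_divergence,
    deamination_rate = cfg_raw$deamination_rate,
    polymerase_error_rate = cfg_raw$polymerase_error_rate,
    clones_per_pcr = cfg_raw$clones_per_pcr,
    pcr_sessions_per_fragment = cfg_raw$pcr_sessions_per_fragment,
    mt_survival_halflife = cfg_raw$mt_survival_halflife,
    nuc_survival_halflife = cfg_raw$nuc_survival_halflife,
    numt_weight = cfg_raw$numt_weight,
    fragments = cfg_raw$fragments,
    samples = cfg_raw$samples,
    numt_stop_free = cfg_raw$numt_stop_free,
    seed = cfg_raw$seed
  )
  attempts <- .read_tsv(file.path(dir, "attempts.tsv"))
  attempts$success <- as.logical(attempts$success)
  lib <- list(clones = cl, attempts = attempts, config = cfg, refs = refs)
  class(lib) <- "clone_library"
  lib
}
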