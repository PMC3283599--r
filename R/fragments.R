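# Designed amplicon layout: 15 short overlapping cytochrome-b fragments
# (97-219 bp including primers) tiling most of the gene, plus 4 fragments of
# IRBP exon 1. Coordinates are 1-based inclusive; cytb fragments sit on the
# cytb reference frame, IRBP fragments on the IRBP reference frame.
# Prime marks in fragment names are encoded in ASCII: C3p = C3', C6pp = C6''.

#' Designed fragment coordinate table
#'
#' The amplification panel used throughout the package: fragment identifier,
#' 1-based inclusive start/end on the gene reference, total length including
#' primers, annealing temperature and gene.
#'
#' @return A data.frame with columns `fragment_id`, `start`, `end`,
#'   `length`, `tm`, `gene`.
#' @examples
#' ft <- fragment_table()
#' all(ft$end - ft$start + 1L == ft$length)
#' @export
fragment_table <- function() {
  ft <- data.frame(
    fragment_id = c("C1", "C2", "C3", "C3p", "C4", "C5", "C6", "C6p", "C6pp",
                    "C7", "C7p", "C8", "C9", "C10", "C11",
                    "I1", "I2", "I3", "I4"),
    start = c(1L, 116L, 237L, 237L, 357L, 472L, 551L, 551L, 551L,
              587L, 587L, 607L, 710L, 789L, 843L,
              887L, 965L, 965L, 1053L),
    end = c(159L, 311L, 349L, 424L, 529L, 647L, 647L, 714L, 769L,
            714L, 769L, 769L, 900L, 941L, 1031L,
            1037L, 1131L, 1087L, 1204L),
    length = c(159L, 196L, 113L, 188L, 173L, 176L, 97L, 164L, 219L,
               128L, 183L, 163L, 191L, 153L, 189L,
               151L, 167L, 123L, 152L),
    tm = c(54L, 50L, 54L, 52L, 52L, 52L, 52L, 52L, 52L,
           52L, 52L, 55L, 42L, 52L, 50L,
           52L, 52L, 52L, 52L),
    stringsAsFactors = FALSE
  )
  ft$gene <- ifelse(startsWith(ft$fragment_id, "I"), "irbp", "cytb")
  ft
}

.check_fragments <- function(fragments) {
  req <- c("fragment_id", "start", "end")
  if (!all(req %in% names(fragments))) {
    stop("fragments need columns: ", paste(req, collapse = ", "))
  }
  if (is.null(fragments$gene)) {
    fragments$gene <- ifelse(startsWith(fragments$fragment_id, "I"),
                             "irbp", "cytb")
  }
  if (any(fragments$end < fragments$start)) stop("fragment end < start")
  if (anyDuplicated(fragments$fragment_id)) stop("duplicate fragment ids")
  fragments$length <- fragments$end - fragments$start + 1L
  fragments
}
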