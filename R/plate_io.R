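#' Read bead-array plate reads from CSV
#'
#' Reads one plate file with columns `well_id, bead_region, bait, prey, mfi,
#' bead_count, replicate`. Each row is one bead region (one bait) read out in
#' one well (one prey); a multiplexed well carries one row per bead region.
#'
#' @param path CSV file path.
#' @param layout optional assay layout used for validation: a list with named
#'   elements `wells` (well_id -> prey name) and `regions` (bead_region ->
#'   bait name), or a path to a YAML file with those two maps. When given,
#'   every `(well_id, bead_region)` in the file must be covered and the
#'   `bait`/`prey` columns must agree with the layout.
#' @return A `data.frame` of validated plate reads with the columns above
#'   (`bead_region`, `bead_count`, `replicate` integer; `mfi` numeric).
#' @examples
#' reads <- data.frame(well_id = "A1", bead_region = 1:2,
#'                     bait = c("P1", "P2"), prey = "P1",
#'                     mfi = c(120, 80), bead_count = 60L, replicate = 1L)
#' f <- tempfile(fileext = ".csv")
#' write_plate(reads, f)
#' identical(read_plate(f), reads)
#' @export
read_plate <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  reads <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("well_id", "bead_region", "bait", "prey", "mfi",
                "bead_count", "replicate")
  missing_cols <- setdiff(required, names(reads))
  if (length(missing_cols)) {
    stop("plate file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  reads <- reads[required]
  suppressWarnings({
    reads$well_id <- as.character(reads$well_id)
    reads$bead_region <- as.integer(reads$bead_region)
    reads$bait <- as.character(reads$bait)
    reads$prey <- as.character(reads$prey)
    reads$mfi <- as.numeric(reads$mfi)
    reads$bead_count <- as.integer(reads$bead_count)
    reads$replicate <- as.integer(reads$replicate)
  })
  validate_reads(reads)
  if (!is.null(layout)) {
    layout <- as_layout(layout)
    bad_well <- setdiff(unique(reads$well_id), names(layout$wells))
    if (length(bad_well)) {
      stop("layout error: well(s) not covered: ",
           paste(bad_well, collapse = ", "))
    }
    bad_region <- setdiff(unique(as.character(reads$bead_region)),
                          names(layout$regions))
    if (length(bad_region)) {
      stop("layout error: bead region(s) not covered: ",
           paste(bad_region, collapse = ", "))
    }
    exp_prey <- unname(layout$wells[reads$well_id])
    exp_bait <- unname(layout$regions[as.character(reads$bead_region)])
    off <- which(reads$prey != exp_prey | reads$bait != exp_bait)
    if (length(off)) {
      stop("layout error: bait/prey identities disagree with layout at data row(s) ",
           paste(utils::head(off, 5), collapse = ", "))
    }
  }
  reads
}

validate_reads <- function(reads) {
  num_bad <- which(!is.finite(reads$mfi) | !is.finite(reads$bead_count) |
                     !is.finite(reads$replicate))
  if (length(num_bad)) {
    stop("parse error: non-numeric mfi/bead_count/replicate at data row(s) ",
         paste(utils::head(num_bad, 5), collapse = ", "))
  }
  neg <- which(reads$mfi < 0)
  if (length(neg)) {
    stop("parse error: negative MFI at data row(s) ",
         paste(utils::head(neg, 5), collapse = ", "))
  }
  if (any(reads$bead_count < 0)) stop("parse error: negative bead count")
  if (any(reads$replicate < 1)) stop("parse error: replicate index < 1")
  if (any(reads$bead_region < 1 | reads$bead_region > 500)) {
    stop("parse error: bead region outside 1-500")
  }
  key <- paste(reads$bead_region, reads$well_id, reads$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("parse error: duplicated (bead_region, well_id, replicate) at data row(s) ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  }
  invisible(reads)
}

as_layout <- function(layout) {
  if (is.character(layout) && length(layout) == 1) {
    layout <- yaml::read_yaml(layout)
  }
  if (!is.list(layout) || !all(c("wells", "regions") %in% names(layout))) {
    stop("layout must have 'wells' and 'regions' maps")
  }
  list(wells = unlist(layout$wells), regions = unlist(layout$regions))
}

#' Write plate reads to CSV
#'
#' @param reads data.frame as returned by [read_plate()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plate <- function(reads, path) {
  validate_reads(reads)
  utils::write.csv(reads, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble plate reads into an interaction matrix
#'
#' Each `(prey, bait)` cell becomes the arithmetic mean of the replicate MFIs
#' that pass the minimum bead-count filter; the filter applies per replicate
#' before averaging. Cells with no passing replicate (or no reads at all) are
#' masked — never imputed. The result is independent of read order, and
#' duplicating every read leaves it unchanged.
#'
#' @param reads plate reads (see [read_plate()]).
#' @param min_beads minimum beads per bead region for a replicate to count;
#'   default 35, the analysis floor of the assay.
#' @return An [interaction_matrix()] over the sorted union of bait and prey
#'   names; rows are prey, columns are bait. A protein seen only as bait (or
#'   only as prey) yields a fully masked row (or column) and a warning.
#' @export
assemble_matrix <- function(reads, min_beads = 35) {
  validate_reads(reads)
  proteins <- sort(unique(c(reads$bait, reads$prey)))
  if (length(proteins) < 2) stop("need at least 2 distinct proteins")
  only_bait <- setdiff(unique(reads$bait), unique(reads$prey))
  only_prey <- setdiff(unique(reads$prey), unique(reads$bait))
  if (length(only_bait)) {
    warning("protein(s) appearing only as bait (fully masked row): ",
            paste(only_bait, collapse = ", "))
  }
  if (length(only_prey)) {
    warning("protein(s) appearing only as prey (fully masked column): ",
            paste(only_prey, collapse = ", "))
  }
  keep <- reads[reads$bead_count >= min_beads, , drop = FALSE]
  N <- length(proteins)
  X <- matrix(NA_real_, N, N, dimnames = list(proteins, proteins))
  if (nrow(keep)) {
    cell <- stats::aggregate(mfi ~ prey + bait, data = keep, FUN = mean)
    X[cbind(match(cell$prey, proteins), match(cell$bait, proteins))] <- cell$mfi
  }
  interaction_matrix(
    X, proteins = proteins,
    meta = list(replicate_rule = "arithmetic mean over passing replicates",
                min_beads = min_beads,
                n_reads = nrow(reads), n_reads_passing = nrow(keep)))
}

#' Wells required to screen an N-protein interactome
#'
#' A one-pair-per-well plate assay needs every ordered or unordered bait-prey
#' combination in its own well, i.e. N^2 wells for an N x N bidirectional
#' screen. A multiplexed bead assay pools all baits in one well, so one well
#' per prey suffices: N wells (plus controls).
#'
#' @param n_proteins number of proteins screened in both roles.
#' @param multiplexed if `TRUE` (default) all baits share a well.
#' @return integer well count.
#' @examples
#' assay_well_count(23, multiplexed = FALSE)  # 529
#' assay_well_count(23)                       # 23
#' @export
assay_well_count <- function(n_proteins, multiplexed = TRUE) {
  stopifnot(is.numeric(n_proteins), n_proteins >= 1)
  n <- as.integer(n_proteins)
  if (multiplexed) n else n * n
}
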