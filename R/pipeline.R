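#' Run the full screen analysis pipeline
#'
#' Orchestrates assemble -> Z-score -> orientation combination -> calling ->
#' quantization -> network construction, writing every artifact plus a JSON
#' manifest of all parameters and seeds into a run directory. A rerun with an
#' identical config reproduces every output bitwise. Any stage failure leaves
#' a `FAILED` marker (stage name and cause) in the run directory and aborts.
#'
#' @param config named list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{matrix}{path to a matrix TSV (exclusive with `plate`)}
#'     \item{plate}{path to a plate CSV (exclusive with `matrix`)}
#'     \item{layout}{optional layout YAML used with `plate`}
#'     \item{min_beads}{bead filter for assembly (default 35)}
#'     \item{B, seed}{bootstrap repetitions (default 300) and root seed
#'       (default 1)}
#'     \item{threshold}{calling threshold (default 5)}
#'     \item{cutoffs}{two quantization percentiles (default 0.80, 0.90)}
#'     \item{subset}{optional list with `rows` and `cols` protein-name
#'       vectors (or paths to one-name-per-line files): restricts the
#'       quantization population to pairs within `rows x cols` and sets the
#'       heat-map block}
#'     \item{overrides}{optional TSV path (protein_a, protein_b,
#'       justification)}
#'     \item{prior}{optional prior edge-list TSV path}
#'     \item{families}{optional TSV path (protein, family)}
#'     \item{outdir}{run directory (created; must be given)}
#'   }
#' @return The run directory path, invisibly. Artifacts: `matrix.tsv`,
#'   `zscores_row.tsv`, `zscores_col.tsv`, `zscores_avg.tsv`, `calls.tsv`,
#'   `heatmap_categories.tsv`, `network_edges.tsv` (+ `.nodes.tsv`),
#'   `network.graphml`, `manifest.json`.
#' @export
run_bpia <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(matrix = NULL, plate = NULL, layout = NULL, min_beads = 35,
         B = 300, seed = 1L, threshold = 5, cutoffs = c(0.80, 0.90),
         subset = NULL, overrides = NULL, prior = NULL, families = NULL,
         outdir = NULL),
    config)
  if (is.null(cfg$outdir)) stop("config must name an 'outdir'")
  has_matrix <- !is.null(cfg$matrix)
  has_plate <- !is.null(cfg$plate)
  if (has_matrix == has_plate) {
    stop("config must name exactly one of 'matrix' or 'plate'")
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  failed <- file.path(cfg$outdir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage: %s\ncause: %s", name,
                         conditionMessage(e)), failed)
      stop(sprintf("pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  m <- stage("assemble", {
    if (has_plate) {
      reads <- read_plate(cfg$plate, layout = cfg$layout)
      assemble_matrix(reads, min_beads = cfg$min_beads)
    } else {
      read_matrix(cfg$matrix)
    }
  })
  write_matrix(m, file.path(cfg$outdir, "matrix.tsv"))

  z <- stage("zscore", zscore_matrix(m, B = cfg$B, seed = cfg$seed))
  stage("zscore", {
    write_z_matrix(z$X_zr, z$proteins, file.path(cfg$outdir, "zscores_row.tsv"))
    write_z_matrix(z$X_zc, z$proteins, file.path(cfg$outdir, "zscores_col.tsv"))
    write_z_matrix(z$X_zrc, z$proteins, file.path(cfg$outdir, "zscores_avg.tsv"))
  })

  scores <- stage("combine", combine_orientations(z))

  subset_rows <- subset_cols <- NULL
  if (!is.null(cfg$subset)) {
    read_names <- function(x) {
      if (is.character(x) && length(x) == 1 && file.exists(x)) {
        readLines(x)
      } else as.character(x)
    }
    subset_rows <- read_names(cfg$subset$rows)
    subset_cols <- read_names(cfg$subset$cols)
    in_block <- (scores$protein_a %in% subset_rows &
                   scores$protein_b %in% subset_cols) |
      (scores$protein_a %in% subset_cols & scores$protein_b %in% subset_rows)
    scores <- scores[in_block, , drop = FALSE]
  }

  overrides <- if (!is.null(cfg$overrides)) {
    utils::read.delim(cfg$overrides, stringsAsFactors = FALSE)
  }
  calls <- stage("call",
                 call_interactions(scores, threshold = cfg$threshold,
                                   overrides = overrides))
  calls <- stage("quantize",
                 quantize_scores(calls, cutoffs = as.numeric(cfg$cutoffs)))
  write_calls(calls, file.path(cfg$outdir, "calls.tsv"))

  stage("heatmap", {
    rows <- if (is.null(subset_rows)) z$proteins else subset_rows
    cols <- if (is.null(subset_cols)) z$proteins else subset_cols
    render_heatmap(calls, rows = rows, cols = cols,
                   path = file.path(cfg$outdir, "heatmap_categories.tsv"))
  })

  prior <- if (!is.null(cfg$prior)) {
    utils::read.delim(cfg$prior, stringsAsFactors = FALSE)
  }
  families <- if (!is.null(cfg$families)) {
    utils::read.delim(cfg$families, stringsAsFactors = FALSE)
  }
  net <- stage("network", build_network(calls, prior = prior,
                                        families = families))
  export_network(net, file.path(cfg$outdir, "network_edges.tsv"),
                 format = "edgelist")
  export_network(net, file.path(cfg$outdir, "network.graphml"),
                 format = "graphml")

  manifest <- list(
    input = if (has_plate) list(plate = cfg$plate, layout = cfg$layout,
                                min_beads = cfg$min_beads)
            else list(matrix = cfg$matrix),
    B = cfg$B, seed = cfg$seed, threshold = cfg$threshold,
    cutoffs = as.numeric(cfg$cutoffs),
    quantize_thresholds = as.numeric(attr(calls, "quantize_thresholds")),
    percentile_convention = attr(calls, "quantize_convention"),
    subset = if (!is.null(cfg$subset)) list(rows = subset_rows,
                                            cols = subset_cols),
    overrides = cfg$overrides, prior = cfg$prior, families = cfg$families,
    n_proteins = length(z$proteins),
    degenerate_rows = z$degenerate_rows,
    degenerate_cols = z$degenerate_cols,
    n_called = sum(calls$called),
    package_version = as.character(utils::packageVersion("plexscreen")))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(cfg$outdir)
}

# write a Z matrix (may contain negatives) in the matrix TSV dialect
write_z_matrix <- function(Z, proteins, path) {
  vals <- matrix("", nrow(Z), ncol(Z))
  ok <- !is.na(Z)
  vals[ok] <- formatC(signif(Z[ok], 6), format = "g", digits = 6)
  lines <- c(paste(c("", proteins), collapse = "\t"),
             vapply(seq_len(nrow(Z)), function(i) {
               paste(c(proteins[i], vals[i, ]), collapse = "\t")
             }, ""))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
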