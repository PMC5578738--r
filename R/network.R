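#' Build an annotated interaction network from called pairs
#'
#' Merges the screen's called pairs with a prior interaction network (e.g.
#' the edge set of an earlier plate-based screen) into one deduplicated,
#' undirected graph whose edges carry a provenance label: `new` (called in
#' this screen only), `confirmed` (called and in the prior set), or
#' `prior_only`. Pairs whose geometric mean is undefined are excluded from
#' the network (their evidence is one-sided) but remain in the calls table.
#'
#' @param calls a [call_interactions()] (optionally quantized) result.
#' @param prior optional prior edges: data.frame with columns `protein_a`,
#'   `protein_b` (order within a pair is ignored; duplicates collapse).
#' @param families optional node annotation: data.frame with columns
#'   `protein`, `family`, or a named character vector. Unannotated nodes get
#'   family `"other"` with a warning.
#' @return An object of class `interaction_network`: list with `nodes`
#'   (data.frame `name`, `family`) and `edges` (data.frame `protein_a`,
#'   `protein_b`, `gmean`, `category`, `called`, `override`, `provenance`).
#' @export
build_network <- function(calls, prior = NULL, families = NULL) {
  stopifnot(inherits(calls, "data.frame"))
  if (!"called" %in% names(calls)) {
    stop("calls must come from call_interactions() (no 'called' column)")
  }
  keep <- calls$called & !is.na(calls$gmean)
  dropped <- calls$called & is.na(calls$gmean)
  if (any(dropped)) {
    warning(sum(dropped), " called pair(s) with undefined geometric mean ",
            "excluded from the network")
  }
  called <- calls[keep, , drop = FALSE]
  # normalize unordered pairs and deduplicate (A::B == B::A)
  norm_pairs <- function(a, b) {
    data.frame(protein_a = pmin(a, b), protein_b = pmax(a, b),
               stringsAsFactors = FALSE)
  }
  cp <- norm_pairs(called$protein_a, called$protein_b)
  first <- !duplicated(paste(cp$protein_a, cp$protein_b, sep = "\r"))
  called <- cbind(cp[first, , drop = FALSE],
                  called[first, setdiff(names(called),
                                        c("protein_a", "protein_b")),
                         drop = FALSE])
  prior_keys <- character(0)
  pp <- NULL
  if (!is.null(prior) && nrow(prior)) {
    if (!all(c("protein_a", "protein_b") %in% names(prior))) {
      stop("prior edges need columns protein_a, protein_b")
    }
    pp <- norm_pairs(prior$protein_a, prior$protein_b)
    pp <- pp[!duplicated(paste(pp$protein_a, pp$protein_b, sep = "\r")), ,
             drop = FALSE]
    prior_keys <- paste(pp$protein_a, pp$protein_b, sep = "\r")
  }
  called_keys <- paste(called$protein_a, called$protein_b, sep = "\r")
  called$provenance <- ifelse(called_keys %in% prior_keys,
                              "confirmed", "new")
  nc <- nrow(called)
  edges <- data.frame(protein_a = called$protein_a,
                      protein_b = called$protein_b,
                      gmean = called$gmean,
                      category = if ("category" %in% names(called)) {
                        as.character(called$category)
                      } else rep(NA_character_, nc),
                      called = rep(TRUE, nc),
                      override = if ("override" %in% names(called)) {
                        called$override
                      } else rep(FALSE, nc),
                      provenance = called$provenance,
                      stringsAsFactors = FALSE)
  if (!is.null(pp)) {
    po <- pp[!(prior_keys %in% called_keys), , drop = FALSE]
    if (nrow(po)) {
      edges <- rbind(edges,
                     data.frame(protein_a = po$protein_a,
                                protein_b = po$protein_b,
                                gmean = NA_real_, category = NA_character_,
                                called = FALSE, override = FALSE,
                                provenance = "prior_only",
                                stringsAsFactors = FALSE))
    }
  }
  rownames(edges) <- NULL
  node_names <- sort(unique(c(edges$protein_a, edges$protein_b,
                              calls$protein_a, calls$protein_b)))
  fam <- rep("other", length(node_names))
  if (!is.null(families)) {
    if (is.data.frame(families)) {
      families <- stats::setNames(as.character(families$family),
                                  families$protein)
    }
    hit <- match(node_names, names(families))
    fam[!is.na(hit)] <- unname(families[hit[!is.na(hit)]])
    miss <- intersect(node_names[is.na(hit)],
                      unique(c(edges$protein_a, edges$protein_b)))
    if (length(miss)) {
      warning("no family annotation for node(s), labelled 'other': ",
              paste(miss, collapse = ", "))
    }
  }
  structure(list(nodes = data.frame(name = node_names, family = fam,
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  tab <- table(factor(x$edges$provenance,
                      levels = c("new", "confirmed", "prior_only")))
  cat(sprintf("interaction_network: %d nodes, %d edges (%d new, %d confirmed, %d prior-only)\n",
              nrow(x$nodes), nrow(x$edges), tab[["new"]], tab[["confirmed"]],
              tab[["prior_only"]]))
  invisible(x)
}

#' Export / import an interaction network
#'
#' `edgelist` writes a TSV of the edge table plus a `<path>.nodes.tsv`
#' companion carrying node annotations (so isolated nodes survive the round
#' trip); `graphml` writes a single GraphML file via igraph with all node and
#' edge attributes. Both formats round-trip losslessly through
#' [import_network()].
#'
#' @param net an [build_network()] result.
#' @param path output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path` (export) or an `interaction_network` (import), invisibly.
#' @export
export_network <- function(net, path, format = c("edgelist", "graphml")) {
  stopifnot(inherits(net, "interaction_network"))
  format <- match.arg(format)
  if (format == "edgelist") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    utils::write.table(net$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a network to an igraph object
#'
#' @param net an [build_network()] result.
#' @return An undirected [igraph::graph] with node attribute `family` and
#'   edge attributes `gmean`, `category`, `called`, `override`, `provenance`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  ed <- net$edges
  # GraphML has no NA; encode before export, decode on import
  ed$category[is.na(ed$category)] <- ""
  ed$gmean[is.na(ed$gmean)] <- -1
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = net$nodes)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    edges <- utils::read.delim(path, stringsAsFactors = FALSE,
                               na.strings = "")
    nodes <- utils::read.delim(paste0(path, ".nodes.tsv"),
                               stringsAsFactors = FALSE, na.strings = "")
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(name = igraph::V(g)$name,
                        family = igraph::V(g)$family,
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(protein_a = pmin(el[, 1], el[, 2]),
                        protein_b = pmax(el[, 1], el[, 2]),
                        gmean = igraph::E(g)$gmean,
                        category = igraph::E(g)$category,
                        called = as.logical(igraph::E(g)$called),
                        override = as.logical(igraph::E(g)$override),
                        provenance = igraph::E(g)$provenance,
                        stringsAsFactors = FALSE)
    edges$category[!nzchar(edges$category) | is.na(edges$category)] <-
      NA_character_
    edges$gmean[edges$gmean < 0] <- NA_real_
  }
  ord <- order(edges$protein_a, edges$protein_b)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "interaction_network")
}

#' Render the quantized category heat map
#'
#' Writes the low/mid/high category matrix for a requested prey x bait
#' protein block (e.g. the 14 x 8 receptor-by-ligand submatrix of a screen)
#' as a TSV; optionally also draws a three-colour image when the pheatmap
#' package is available. Pair categories are symmetric, so the cell for
#' (row r, column c) is the category of the unordered pair {r, c}.
#'
#' @param scores a [quantize_scores()] result.
#' @param rows,cols character vectors of protein names for the heat-map rows
#'   and columns. Any name absent from `scores` is an error listing it.
#' @param path output TSV path.
#' @param image optional PNG path for a rendered image (requires pheatmap;
#'   skipped with a message otherwise).
#' @return The category matrix (character, rows x cols), invisibly.
#' @export
render_heatmap <- function(scores, rows, cols, path, image = NULL) {
  stopifnot(inherits(scores, "data.frame"))
  if (!"category" %in% names(scores)) {
    stop("scores must be quantized first (no 'category' column)")
  }
  known <- unique(c(scores$protein_a, scores$protein_b))
  absent <- setdiff(c(rows, cols), known)
  if (length(absent)) {
    stop("protein(s) absent from scores: ", paste(absent, collapse = ", "))
  }
  key <- pair_key(scores$protein_a, scores$protein_b)
  grid <- expand.grid(r = rows, c = cols, stringsAsFactors = FALSE)
  hit <- match(pair_key(grid$r, grid$c), key)
  if (anyNA(hit)) {
    bad <- grid[is.na(hit), , drop = FALSE]
    stop("pair(s) missing from scores: ",
         paste(paste(bad$r, bad$c, sep = "::"), collapse = ", "))
  }
  cats <- matrix(as.character(scores$category[hit]), nrow = length(rows),
                 dimnames = list(rows, cols))
  lines <- c(paste(c("", cols), collapse = "\t"),
             vapply(seq_along(rows), function(i) {
               paste(c(rows[i], cats[i, ]), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  if (!is.null(image)) {
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      num <- matrix(match(cats, c("low", "mid", "high")), nrow(cats),
                    dimnames = dimnames(cats))
      grDevices::png(image, width = 640, height = 780)
      pheatmap::pheatmap(num, cluster_rows = FALSE, cluster_cols = FALSE,
                         legend = FALSE,
                         color = c("white", "lightblue", "darkblue"))
      grDevices::dev.off()
    } else {
      message("pheatmap not installed; image skipped")
    }
  }
  invisible(cats)
}
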