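extdata <- function(f) system.file("extdata", f, package = "plexscreen")

prior_edges <- function() {
  utils::read.delim(extdata("ecia_prior_edges.tsv"),
                    stringsAsFactors = FALSE)
}

families_map <- function() {
  utils::read.delim(extdata("beat_side_families.tsv"),
                    stringsAsFactors = FALSE)
}

# calls table covering all prior edges plus the three newly discovered pairs
revised_screen_calls <- function() {
  prior <- prior_edges()
  new <- data.frame(protein_a = c("Beat-VI", "Beat-Ic", "Beat-Ic"),
                    protein_b = c("Side-II", "Side", "Side-III"))
  all <- rbind(prior, new)
  data.frame(all, z_ab = 10, z_ba = 10, gmean = seq(6, 5 + nrow(all)),
             called = TRUE, override = FALSE, justification = "")
}

test_that("merging calls with the prior network labels exactly the new edges", {
  net <- build_network(revised_screen_calls(), prior = prior_edges(),
                       families = families_map())
  new_edges <- net$edges[net$edges$provenance == "new", ]
  got <- sort(paste(new_edges$protein_a, new_edges$protein_b, sep = "::"))
  expect_identical(got, sort(c("Beat-VI::Side-II", "Beat-Ic::Side",
                               "Beat-Ic::Side-III")))
  expect_equal(sum(net$edges$provenance == "confirmed"), nrow(prior_edges()))
  expect_equal(sum(net$edges$provenance == "prior_only"), 0)
  fams <- setNames(net$nodes$family, net$nodes$name)
  expect_identical(unname(fams[c("Beat-VI", "Side-II", "CG17839")]),
                   c("Beat", "Side", "other"))
})

test_that("edge provenance partitions the edge set", {
  calls <- revised_screen_calls()
  calls$called[1:3] <- FALSE  # drop some screen support
  net <- build_network(calls, prior = prior_edges(),
                       families = families_map())
  expect_true(all(net$edges$provenance %in%
                    c("new", "confirmed", "prior_only")))
  key <- paste(net$edges$protein_a, net$edges$protein_b)
  expect_false(anyDuplicated(key) > 0)
  # every endpoint is a node
  expect_true(all(c(net$edges$protein_a, net$edges$protein_b) %in%
                    net$nodes$name))
  # prior-only edges are exactly the dropped ones
  expect_equal(sum(net$edges$provenance == "prior_only"), 3)
})

test_that("empty calls give a prior-only network; reversed duplicates collapse", {
  empty <- revised_screen_calls()[0, ]
  net <- build_network(empty, prior = prior_edges())
  expect_true(all(net$edges$provenance == "prior_only"))
  expect_equal(nrow(net$edges), nrow(prior_edges()))

  dup <- data.frame(protein_a = c("X", "Y"), protein_b = c("Y", "X"),
                    z_ab = 8, z_ba = 8, gmean = 8, called = TRUE,
                    override = FALSE, justification = "")
  net2 <- build_network(dup)
  expect_equal(nrow(net2$edges), 1)

  # called pair with undefined gmean is excluded, with a warning
  und <- data.frame(protein_a = "X", protein_b = "Y", z_ab = 9, z_ba = 0,
                    gmean = NA_real_, called = TRUE, override = TRUE,
                    justification = "curator")
  expect_warning(net3 <- build_network(und), "undefined geometric mean")
  expect_equal(nrow(net3$edges), 0)
})

test_that("network exports round-trip through edge-list TSV and GraphML", {
  calls <- revised_screen_calls()
  calls$category <- factor(c(rep("high", 9), rep("mid", 3)),
                           levels = c("low", "mid", "high"), ordered = TRUE)
  net <- build_network(calls, prior = prior_edges(),
                       families = families_map())
  f1 <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, f1, format = "edgelist")
  back1 <- import_network(f1, format = "edgelist")
  f2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f2, format = "graphml")
  back2 <- import_network(f2, format = "graphml")

  ref_edges <- net$edges[order(net$edges$protein_a, net$edges$protein_b), ]
  rownames(ref_edges) <- NULL
  ref_nodes <- net$nodes[order(net$nodes$name), ]
  rownames(ref_nodes) <- NULL
  for (back in list(back1, back2)) {
    expect_equal(back$edges, ref_edges)
    expect_equal(back$nodes, ref_nodes)
  }
  # GraphML is schema-valid XML with graphml root
  doc <- xml2::read_xml(f2)
  expect_match(xml2::xml_name(doc), "graphml")

  e0 <- net; e0$edges <- e0$edges[0, ]
  f3 <- withr::local_tempfile(fileext = ".tsv")
  export_network(e0, f3, format = "edgelist")
  expect_equal(length(readLines(f3)), 1)  # header only
  expect_error(export_network(net, f1, format = "dot"), "arg")
})

test_that("the quantized heat map covers the requested block", {
  scr <- demo_screen(seed = 91, n_a = 6, n_b = 4, n_edges = 3)
  calls <- quantize_scores(call_interactions(combine_orientations(
    zscore_matrix(scr$matrix, B = 150, seed = 2))))
  rows <- scr$truth$proteins$name[scr$truth$proteins$family == "Rec"]
  cols <- scr$truth$proteins$name[scr$truth$proteins$family == "Lig"]
  f <- withr::local_tempfile(fileext = ".tsv")
  cats <- render_heatmap(calls, rows, cols, f)
  expect_equal(dim(cats), c(6, 4))
  expect_true(all(cats %in% c("low", "mid", "high")))
  tab <- utils::read.delim(f, row.names = 1, check.names = FALSE)
  expect_equal(dim(tab), c(6, 4))

  one <- render_heatmap(calls, rows[1], cols[1],
                        withr::local_tempfile(fileext = ".tsv"))
  expect_equal(dim(one), c(1, 1))
  expect_error(render_heatmap(calls, c(rows, "Unobtainium"), cols, f),
               "Unobtainium")
})

test_that("all-undefined scores quantize to an all-low heat map", {
  sc <- data.frame(protein_a = c("A", "A", "B"), protein_b = c("A", "B", "B"),
                   z_ab = -1, z_ba = -1, gmean = NA_real_)
  suppressWarnings(q <- quantize_scores(call_interactions(sc)))
  f <- withr::local_tempfile(fileext = ".tsv")
  cats <- render_heatmap(q, c("A", "B"), c("A", "B"), f)
  expect_true(all(cats == "low"))
})
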