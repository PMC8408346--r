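# Tree serialization: versioned JSON (lossless round trip) and Graphviz
# DOT with the conventional node annotations (samples, samples by class,
# predicted class, split feature and threshold).

.node_to_list <- function(node) {
  out <- list(
    samples = node$samples,
    samples_by_class = node$samples_by_class,
    predicted_class = node$predicted_class,
    gini = node$gini,
    leaf = node$leaf
  )
  if (!node$leaf) {
    out$feature <- node$feature
    out$threshold <- node$threshold
    out$left <- .node_to_list(node$left)
    out$right <- .node_to_list(node$right)
  }
  out
}

.node_from_list <- function(x) {
  node <- list(
    samples = as.integer(x$samples),
    samples_by_class = as.integer(unlist(x$samples_by_class)),
    predicted_class = x$predicted_class,
    gini = as.numeric(x$gini),
    leaf = isTRUE(x$leaf)
  )
  if (!node$leaf) {
    node$feature <- x$feature
    node$threshold <- as.numeric(x$threshold)
    node$left <- .node_from_list(x$left)
    node$right <- .node_from_list(x$right)
  }
  node
}

#' Serialize a guideline tree
#'
#' `export_tree_json()` writes a versioned, lossless JSON document;
#' `import_tree_json()` reads it back (round-trip identity on structure,
#' counts and thresholds). `export_tree_dot()` renders Graphviz DOT with
#' one box per node carrying samples, samples by class, predicted class
#' and, for split nodes, the `feature <= threshold` test (thresholds
#' printed rounded to 3 decimals; stored precision is unaffected).
#'
#' @param tree a `qc_tree`
#' @param path output path; omit to return the text
#' @return The JSON/DOT text (invisibly when written to `path`).
#' @export
export_tree_json <- function(tree, path = NULL) {
  doc <- list(
    schema = "seqguide-tree/1",
    max_depth = tree$max_depth,
    degenerate = isTRUE(tree$degenerate),
    root = .node_to_list(tree$root)
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname export_tree_json
#' @param json a path to, or the text of, a tree JSON document
#' @export
import_tree_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (is.null(doc$schema) || !startsWith(doc$schema, "seqguide-tree/")) {
    abort("not a seqguide tree document")
  }
  root <- .node_from_list(doc$root)
  structure(
    list(
      root = root,
      max_depth = as.integer(doc$max_depth),
      features = unique(stats::na.omit(.tree_nodes(root)$feature)),
      degenerate = isTRUE(doc$degenerate)
    ),
    class = "qc_tree"
  )
}

#' @rdname export_tree_json
#' @export
export_tree_dot <- function(tree, path = NULL) {
  nodes <- tidy(tree)
  label <- vapply(seq_len(nrow(nodes)), function(i) {
    r <- nodes[i, ]
    base <- paste0(
      "samples = ", r$samples, "\\n",
      "samples by class = [", r$n_high, ", ", r$n_low, "]\\n",
      "predicted class = ", r$predicted_class
    )
    if (!r$leaf) {
      base <- paste0(base, "\\n", r$feature, " <= ", round(r$threshold, 3))
    }
    base
  }, character(1))
  body <- c(
    "digraph qc_tree {",
    "  node [shape=box, fontname=\"Helvetica\"];",
    paste0("  n", nodes$node, " [label=\"", label, "\"];"),
    paste0(
      "  n", nodes$parent[!is.na(nodes$parent)], " -> n",
      nodes$node[!is.na(nodes$parent)],
      ifelse(nodes$node[!is.na(nodes$parent)] %% 2 == 0,
        " [label=\"yes\"];", " [label=\"no\"];"
      )
    ),
    "}"
  )
  txt <- paste(body, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
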