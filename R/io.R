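#' Read an expression matrix from TSV/CSV
#'
#' The delimiter is chosen from the file extension (`.csv` uses a comma,
#' anything else a tab). The file must have a header row and row
#' identifiers in the first column; missing values and duplicated gene
#' identifiers are errors.
#'
#' @param path file path.
#' @param orientation `"samples_x_genes"` (default) or `"genes_x_samples"`
#'   (the matrix is transposed after reading so the result is always
#'   samples x genes).
#' @return numeric matrix, samples in rows, genes in columns, both named.
#' @export
readExpression <- function(path,
                           orientation = c("samples_x_genes",
                                           "genes_x_samples")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df)
  if (!is.numeric(M)) {
    bad <- which(!vapply(df, is.numeric, TRUE))
    stop("non-numeric values in column(s): ",
         paste(colnames(df)[bad], collapse = ", "))
  }
  if (anyNA(M)) {
    idx <- which(is.na(M), arr.ind = TRUE)
    stop("missing values at: ",
         paste(sprintf("[%s, %s]", rownames(M)[idx[, 1]],
                       colnames(M)[idx[, 2]]), collapse = ", "))
  }
  if (orientation == "genes_x_samples") M <- t(M)
  if (anyDuplicated(colnames(M)))
    stop("duplicated gene identifiers: ",
         paste(unique(colnames(M)[duplicated(colnames(M))]), collapse = ", "))
  M
}

#' Read a STRING-style prior interaction score table
#'
#' Expects three columns (gene_a, gene_b, score). Scores are scaled to
#' `[0, 1]`: with `scaleMode = "auto"` (default), any score above 1
#' triggers the STRING 0-1000 convention (divide by 1000, with a message);
#' `"unit"` takes scores as-is and `"string1000"` always divides by 1000.
#'
#' @param path file path (TSV, or CSV by extension).
#' @param scaleMode `"auto"`, `"unit"` or `"string1000"`.
#' @return data.frame with columns `geneA`, `geneB`, `score` (in `[0, 1]`).
#' @export
readPriorTable <- function(path, scaleMode = c("auto", "unit",
                                               "string1000")) {
  scaleMode <- match.arg(scaleMode)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("prior table needs columns gene_a, gene_b, score")
  out <- data.frame(geneA = as.character(df[[1]]),
                    geneB = as.character(df[[2]]),
                    score = as.numeric(df[[3]]))
  if (scaleMode == "auto" && any(out$score > 1)) {
    message("scores above 1 detected; assuming the 0-1000 STRING ",
            "convention and dividing by 1000")
    scaleMode <- "string1000"
  }
  if (scaleMode == "string1000") out$score <- out$score / 1000
  if (any(out$score < 0 | out$score > 1))
    stop("scores outside [0, 1] after scaling")
  out
}

#' Assemble a weight matrix from a prior score table
#'
#' Aligns prior records to `geneIds`: unseen pairs and self-pairs get 0,
#' duplicated pairs (in either orientation) keep the maximum score, and
#' prior genes absent from `geneIds` are dropped with a message.
#'
#' @param prior data.frame as returned by [readPriorTable()] (columns
#'   `geneA`, `geneB`, `score` in `[0, 1]`).
#' @param geneIds unique character vector of gene identifiers.
#' @return symmetric p x p weight matrix with `geneIds` dimnames.
#' @export
buildWeightMatrix <- function(prior, geneIds) {
  if (anyDuplicated(geneIds)) stop("'geneIds' must be unique")
  if (any(prior$score < 0 | prior$score > 1))
    stop("prior scores must lie in [0, 1]")
  p <- length(geneIds)
  W <- matrix(0, p, p, dimnames = list(geneIds, geneIds))
  ia <- match(prior$geneA, geneIds)
  ib <- match(prior$geneB, geneIds)
  drop <- is.na(ia) | is.na(ib)
  if (any(drop))
    message(sum(drop), " prior record(s) with genes outside the gene set ",
            "ignored")
  ia <- ia[!drop]; ib <- ib[!drop]; sc <- prior$score[!drop]
  self <- ia == ib
  ia <- ia[!self]; ib <- ib[!self]; sc <- sc[!self]
  for (k in seq_along(sc)) {
    i <- ia[k]; j <- ib[k]
    if (sc[k] > W[i, j]) W[i, j] <- W[j, i] <- sc[k]
  }
  W
}

#' Write a network to disk
#'
#' Formats: `"tsv"` writes a two-column edge list (gene_a, gene_b),
#' lexicographically sorted and round-trip safe via [readNetwork()];
#' `"sif"` uses the interaction type `pp`; `"graphml"` delegates to
#' igraph.
#'
#' @param net a [GeneNetwork-class].
#' @param path output file.
#' @param fmt `"tsv"`, `"sif"` or `"graphml"`.
#' @return the path, invisibly.
#' @export
writeNetwork <- function(net, path, fmt = c("tsv", "sif", "graphml")) {
  fmt <- match.arg(fmt)
  nodes <- nodeNames(net)
  E <- edgeMatrix(net)
  a <- nodes[E[, 1]]; b <- nodes[E[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  o <- order(a, b)
  a <- a[o]; b <- b[o]
  if (fmt == "tsv") {
    utils::write.table(data.frame(gene_a = a, gene_b = b), path,
                       sep = "\t", quote = TRUE, row.names = FALSE)
  } else if (fmt == "sif") {
    writeLines(if (length(a)) paste(a, "pp", b, sep = "\t") else character(),
               path)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = a, to = b),
      directed = FALSE,
      vertices = data.frame(name = nodes))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back a TSV edge list written by [writeNetwork()]
#'
#' @param path file path.
#' @param nodes node set of the network (needed because isolated nodes do
#'   not appear in the edge list).
#' @return a [GeneNetwork-class].
#' @export
readNetwork <- function(path, nodes) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ia <- match(df$gene_a, nodes)
  ib <- match(df$gene_b, nodes)
  if (anyNA(ia) || anyNA(ib)) stop("edge list contains unknown nodes")
  pairs <- cbind(i = pmin(ia, ib), j = pmax(ia, ib))
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  makeGeneNetwork(pairs, nodes)
}

#' Write a JSON run manifest
#'
#' Records all parameters, seeds and input-file checksums of a run so it
#' can be repeated bit-identically.
#'
#' @param path output JSON path.
#' @param parameters named list of parameters/seeds.
#' @param inputs character vector of input file paths (md5-summed).
#' @return the path, invisibly.
#' @export
writeManifest <- function(path, parameters, inputs = character()) {
  manifest <- list(
    parameters = parameters,
    inputs = lapply(stats::setNames(as.list(inputs), basename(inputs)),
                    function(f) list(path = f, md5 = unname(tools::md5sum(f)))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
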