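#' Read a time-series table from a delimited text file
#'
#' Expects a header row of unique variable names and a numeric body; the
#' delimiter (comma or tab) is auto-detected unless given. A first column
#' whose header is one of `time`, `t`, `date`, `index`, `step` (case
#' insensitive) is treated as a time stamp and dropped from the variables.
#' Missing or non-numeric cells are rejected with the offending row and
#' column in the message.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects `,` vs tab.
#' @return A [time_series_set()].
#' @export
read_timeseries_table <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    oif_error(sprintf("file not found: %s", path), "oifnet_io_error")
  }
  first <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  nm <- names(df)
  if (anyDuplicated(nm)) {
    oif_error(sprintf("duplicate column names: %s",
                      paste(unique(nm[duplicated(nm)]), collapse = ", ")),
              "oifnet_io_error")
  }
  time_col <- tolower(nm[1]) %in% c("time", "t", "date", "index", "step")
  if (time_col) df <- df[, -1, drop = FALSE]
  if (ncol(df) < 2) {
    oif_error("need at least 2 variables for pairwise inference",
              "oifnet_io_error")
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      oif_error(sprintf("non-numeric cell at row %d, column '%s'",
                        bad, names(df)[j]), "oifnet_io_error")
    }
    if (anyNA(col)) {
      oif_error(sprintf("missing value at row %d, column '%s'",
                        which(is.na(col))[1], names(df)[j]),
                "oifnet_io_error")
    }
  }
  time_series_set(as.matrix(df))
}

#' Write a time-series table to a delimited text file
#'
#' @param ts a [time_series_set()].
#' @param path output path.
#' @param sep field separator (default comma).
#' @param time_index include a leading integer `time` column (default
#'   `TRUE`).
#' @return `path`, invisibly.
#' @export
write_timeseries_table <- function(ts, path, sep = ",", time_index = TRUE) {
  ts <- as_time_series_set(ts)
  df <- as.data.frame(ts$values)
  if (time_index) df <- cbind(time = seq_len(nrow(df)), df)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write an interaction network to a file
#'
#' Formats: `"matrix_csv"` (labeled S x S matrix), `"edge_list"` (directed
#' weighted edges `source,target,weight`, zeros implicit, species set
#' recorded in a header comment so the matrix round-trips exactly), or
#' `"graphml"` (directed weighted graph via igraph).
#'
#' @param m an [interaction_matrix()].
#' @param path output path.
#' @param format one of `"matrix_csv"`, `"edge_list"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(m, path,
                          format = c("matrix_csv", "edge_list", "graphml")) {
  stopifnot(inherits(m, "interaction_matrix"))
  format <- match.arg(format)
  v <- m$values
  if (format == "matrix_csv") {
    utils::write.csv(v, path, quote = FALSE)
  } else if (format == "edge_list") {
    nz <- which(v != 0 & row(v) != col(v), arr.ind = TRUE)
    edges <- data.frame(source = rownames(v)[nz[, 1]],
                        target = colnames(v)[nz[, 2]],
                        weight = v[nz])
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# species: %s", paste(rownames(v), collapse = "|")),
               con)
    utils::write.table(edges, con, sep = ",", row.names = FALSE,
                       quote = FALSE)
  } else {
    gr <- igraph::graph_from_adjacency_matrix(v, mode = "directed",
                                              weighted = TRUE, diag = FALSE)
    igraph::write_graph(gr, path, format = "graphml")
  }
  invisible(path)
}

#' Read an interaction network from an edge-list file
#'
#' Inverse of [write_network()] with `format = "edge_list"`: reconstructs
#' the full matrix (zeros implicit) from the species set recorded in the
#' header comment.
#'
#' @param path edge-list file written by [write_network()].
#' @param method method label for the reconstructed matrix.
#' @return An [interaction_matrix()].
#' @export
read_network_edge_list <- function(path, method = "te") {
  if (!file.exists(path)) {
    oif_error(sprintf("file not found: %s", path), "oifnet_io_error")
  }
  first <- readLines(path, n = 1L)
  if (!grepl("^# species:", first)) {
    oif_error("missing '# species:' header comment", "oifnet_io_error")
  }
  species <- strsplit(sub("^# species: ", "", first), "|",
                      fixed = TRUE)[[1]]
  edges <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  v <- matrix(0, length(species), length(species),
              dimnames = list(species, species))
  if (nrow(edges) > 0) {
    v[cbind(match(edges$source, species),
            match(edges$target, species))] <- edges$weight
  }
  interaction_matrix(v, method = method, species_names = species)
}

#' Write and read a run configuration
#'
#' A run configuration is a plain named list (simulator or input settings,
#' estimator parameters, seeds, output paths) serialized as YAML so a run
#' can be archived and re-executed exactly.
#'
#' @param config named list.
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    oif_error(sprintf("file not found: %s", path), "oifnet_io_error")
  }
  yaml::read_yaml(path)
}
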