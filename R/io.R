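# Plain-text serialization. Matrices travel as TSV (row per line, no
# header, full precision) or JSON (nested arrays); patterns and reports
# as JSON; networks as edge lists. All indices in files are 1-based and
# files say so.

.fmt_from_path <- function(file) {
  if (grepl("\\.json$", file, ignore.case = TRUE)) "json" else "tsv"
}

#' Write a numeric matrix to TSV or JSON
#'
#' TSV files are tab-separated, one row per line, no header, with 17
#' significant digits so round trips preserve doubles exactly. `.json`
#' extensions switch to nested-array JSON.
#'
#' @param x A numeric matrix.
#' @param file Output path; the extension selects the format.
#' @export
write_matrix <- function(x, file) {
  x <- as.matrix(x)
  if (.fmt_from_path(file) == "json") {
    jsonlite::write_json(apply(x, 1L, function(r) r, simplify = FALSE),
                         file, digits = NA, auto_unbox = FALSE)
  } else {
    lines <- apply(x, 1L, function(r) {
      paste(formatC(r, digits = 17, format = "g"), collapse = "\t")
    })
    writeLines(lines, file)
  }
  invisible(file)
}

#' Read a numeric matrix written by [write_matrix()]
#'
#' @param file Path to a `.tsv`/`.txt` or `.json` matrix file.
#' @return A numeric matrix.
#' @export
read_matrix <- function(file) {
  if (.fmt_from_path(file) == "json") {
    rows <- jsonlite::read_json(file, simplifyVector = TRUE)
    if (is.list(rows)) rows <- do.call(rbind, rows)
    as.matrix(rows)
  } else {
    as.matrix(utils::read.table(file, sep = "\t", header = FALSE,
                                comment.char = "#"))
  }
}

#' Write a structural zero pattern as JSON
#'
#' The file records the Jacobian dimension, the index base (always
#' 1-based), and the list of `[row, col]` positions.
#'
#' @param pattern A [zero_pattern()].
#' @param file Output path.
#' @export
write_zero_pattern <- function(pattern, file) {
  stopifnot(inherits(pattern, "zero_pattern"))
  obj <- list(
    n = pattern$n,
    indexing = "1-based",
    vec_convention = "column-stacking",
    positions = unname(apply(pattern$positions, 1L, function(r)
      as.integer(r), simplify = FALSE))
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE)
  invisible(file)
}

#' Read a structural zero pattern from JSON
#'
#' @param file Path written by [write_zero_pattern()].
#' @return A [zero_pattern()].
#' @export
read_zero_pattern <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  pos <- obj$positions
  if (is.list(pos)) pos <- do.call(rbind, pos)
  if (length(pos) == 0L) pos <- NULL
  zero_pattern(pos, obj$n)
}

#' Write a patch network as a plain-text edge list
#'
#' One `u v` pair per line (1-based), preceded by comment lines with
#' the node count.
#'
#' @param net A [patch_network()].
#' @param file Output path.
#' @export
write_edge_list <- function(net, file) {
  stopifnot(inherits(net, "patch_network"))
  header <- c("# patch network edge list (1-based indices)",
              paste0("# nodes: ", net$n_nodes))
  body <- apply(net$edges, 1L, function(e) paste(e[1L], e[2L]))
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param file Path to the edge-list file.
#' @param n_nodes Node count; if `NULL`, taken from the `# nodes:`
#'   header comment (falling back to the largest index seen).
#' @return A [patch_network()].
#' @export
read_edge_list <- function(file, n_nodes = NULL) {
  lines <- readLines(file)
  if (is.null(n_nodes)) {
    hdr <- grep("^#\\s*nodes:", lines, value = TRUE)
    if (length(hdr)) {
      n_nodes <- as.integer(sub("^#\\s*nodes:\\s*", "", hdr[1L]))
    }
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  edges <- if (length(body)) {
    do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), function(p)
      as.integer(p[1:2])))
  } else {
    NULL
  }
  if (is.null(n_nodes)) n_nodes <- max(edges)
  patch_network(edges, n_nodes)
}

#' Write a simulated time series as TSV with provenance
#'
#' Comment lines (`#`) record the seed, step size, stride, burn-in and
#' any ramped parameter; the header line names the time column and the
#' variables; data rows follow in full precision.
#'
#' @param ts A `sim_ts`.
#' @param file Output path.
#' @export
write_time_series <- function(ts, file) {
  stopifnot(inherits(ts, "sim_ts"))
  prov <- c(
    "# jacrecon time series",
    paste0("# seed: ", ts$config$seed),
    paste0("# dt: ", formatC(ts$config$dt, digits = 17, format = "g")),
    paste0("# stride: ", ts$config$stride),
    paste0("# burn_in: ", ts$config$burn_in),
    paste0("# noise_mode: ", ts$noise$mode),
    paste0("# noise_sigma: ",
           paste(formatC(ts$noise$sigma, digits = 17, format = "g"),
                 collapse = ",")),
    if (!is.null(ts$param_name)) paste0("# ramp: ", ts$param_name)
  )
  cols <- cbind(time = ts$times, ts$values)
  colnames(cols) <- c("time", ts$labels)
  if (!is.null(ts$param_trace)) {
    cols <- cbind(cols, param = ts$param_trace)
  }
  header <- paste(colnames(cols), collapse = "\t")
  body <- apply(cols, 1L, function(r) {
    paste(formatC(r, digits = 17, format = "g"), collapse = "\t")
  })
  writeLines(c(prov, header, body), file)
  invisible(file)
}

#' Read a time series written by [write_time_series()]
#'
#' @param file Path to the TSV file.
#' @return A list with `times`, `values`, `labels`, `param_trace` (or
#'   `NULL`) and `provenance` (the raw comment lines). Usable wherever
#'   a matrix of fluctuations is accepted.
#' @export
read_time_series <- function(file) {
  lines <- readLines(file)
  prov <- grep("^#", lines, value = TRUE)
  tab <- utils::read.table(text = lines[!grepl("^#", lines)],
                           header = TRUE, sep = "\t",
                           check.names = FALSE)
  has_param <- "param" %in% names(tab)
  vals <- as.matrix(tab[, setdiff(names(tab), c("time", "param")),
                        drop = FALSE])
  list(times = tab$time, values = vals,
       labels = colnames(vals),
       param_trace = if (has_param) tab$param else NULL,
       provenance = prov)
}

#' Serialize a reconstruction result as a JSON report
#'
#' @param result A `jac_reconstruction`.
#' @param file Output path.
#' @export
write_reconstruction_report <- function(result, file) {
  stopifnot(inherits(result, "jac_reconstruction"))
  obj <- list(
    jacobian = apply(result$jacobian, 1L, function(r) r,
                     simplify = FALSE),
    residual_norm = result$residual_norm,
    rank_flag = if (result$rank_deficient) "rank-deficient" else "full-rank",
    eigenvalues = lapply(result$eigenvalues, function(z)
      c(Re(z), Im(z))),
    leading_eigenvalue = c(Re(result$leading_eigenvalue),
                           Im(result$leading_eigenvalue)),
    leading_type = result$leading_type,
    zeros_enforced = result$zeros_enforced,
    underdetermined = result$underdetermined
  )
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}
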