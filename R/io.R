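#' Read a panel from delimited text plus a families sidecar
#'
#' The panel file is comma-separated UTF-8 text with a mandatory header row
#' and one column per series (use `transpose = TRUE` for one row per
#' series). The sidecar maps every series name to its family label and,
#' optionally, a dispersion override; it is YAML or JSON, either
#' `name: family` pairs or `name: {family: ..., dispersion: ...}` entries.
#' All family-domain checks of [ts_panel()] are applied, and violations are
#' reported with the offending series named.
#'
#' @param path Path of the delimited panel file.
#' @param families_path Path of the YAML/JSON sidecar. Alternatively pass
#'   `families` directly.
#' @param families Character vector of family labels (used when no sidecar
#'   is given).
#' @param transpose Panel stored with series in rows.
#' @return A [ts_panel()]; any dispersion overrides are attached as the
#'   `"dispersion"` attribute.
#' @export
read_panel <- function(path, families_path = NULL, families = NULL,
                       transpose = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (transpose) {
    nms <- as.character(df[[1]])
    values <- t(as.matrix(df[, -1]))
    colnames(values) <- nms
    df <- as.data.frame(values)
  }
  dispersion <- NULL
  if (!is.null(families_path)) {
    cfg <- read_families_config(families_path)
    families <- cfg$families
    dispersion <- cfg$dispersion
  }
  if (is.null(families)) {
    stop("supply `families` or `families_path`", call. = FALSE)
  }
  panel <- ts_panel(df, families)
  if (!is.null(dispersion)) attr(panel, "dispersion") <- dispersion
  panel
}

read_families_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  families <- character(0)
  dispersion <- numeric(0)
  for (nm in names(cfg)) {
    entry <- cfg[[nm]]
    if (is.list(entry)) {
      families[nm] <- entry$family
      if (!is.null(entry$dispersion)) {
        dispersion[nm] <- as.numeric(entry$dispersion)
      }
    } else {
      families[nm] <- as.character(entry)
    }
  }
  list(families = families,
       dispersion = if (length(dispersion)) dispersion else NULL)
}

#' Write a panel (and optionally its families sidecar) to delimited text
#'
#' @param panel A [ts_panel()].
#' @param path Output CSV path.
#' @param families_path Optional YAML path for the families sidecar.
#' @return `panel`, invisibly.
#' @export
write_panel <- function(panel, path, families_path = NULL) {
  stopifnot(inherits(panel, "ts_panel"))
  readr::write_csv(tibble::as_tibble(as.data.frame(panel$values)), path,
                   progress = FALSE)
  if (!is.null(families_path)) {
    yaml::write_yaml(as.list(panel$families), families_path)
  }
  invisible(panel)
}

#' Write a causal graph as an adjacency matrix and edge list
#'
#' The adjacency CSV has a `series` column of target names followed by one
#' 0/1 column per series (entry `(i, j)` = series `j` causes series `i`);
#' [read_graph()] restores it exactly. The edge-list CSV has columns
#' `cause`, `effect` and `row_score` (the minimised message length of the
#' effect's selection, when available).
#'
#' @param graph A [causal_graph()].
#' @param path Output path for the adjacency CSV.
#' @param edges_path Optional output path for the edge list.
#' @return `graph`, invisibly.
#' @export
write_graph <- function(graph, path, edges_path = NULL) {
  stopifnot(inherits(graph, "causal_graph"))
  adj <- graph$adjacency
  out <- tibble::as_tibble(as.data.frame(adj + 0L))
  out <- dplyr::bind_cols(tibble::tibble(series = rownames(adj)), out)
  readr::write_csv(out, path, progress = FALSE)
  if (!is.null(edges_path)) {
    readr::write_csv(tidy.causal_graph(graph), edges_path, progress = FALSE)
  }
  invisible(graph)
}

#' Read a causal graph written by [write_graph()]
#'
#' @param path Adjacency CSV path.
#' @return A [causal_graph()].
#' @export
read_graph <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nms <- as.character(df$series)
  adj <- as.matrix(df[, setdiff(names(df), "series")]) > 0
  dimnames(adj) <- list(nms, colnames(adj))
  causal_graph(adj)
}

#' Export the score decomposition of a selection as a JSON record
#'
#' Audit trail for one per-target selection: target, candidate bitstring,
#' optimal lambda, the term-by-term decomposition of the message length and
#' its total.
#'
#' @param selection An `hggm_selection`.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
export_score_json <- function(selection, path = NULL) {
  stopifnot(inherits(selection, "hggm_selection"))
  sc <- selection$mml
  rec <- list(
    target = selection$target_name,
    method = selection$method,
    Q = paste(as.integer(selection$Q), collapse = ""),
    lambda = selection$lambda,
    decomposition = sc[c("neg_log_lik", "fisher_logdet", "prior_terms",
                         "constant_terms", "structure_code")],
    total = selection$score
  )
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
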