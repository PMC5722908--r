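#' Build a campaign run ledger (manifest)
#'
#' A manifest records one row per simulation group: group id, method tag,
#' a note on the starting structure, the production time per run in
#' nanoseconds and the number of replicate runs. The bundled Cas9
#' campaign ledger is available via [cas9_run_ledger()].
#'
#' @param group character group ids.
#' @param method character method tags (e.g. `"cMD"`, `"aMD_dual"`,
#'   `"tMD"`, `"cMDens"`).
#' @param start_note free-text starting-structure notes.
#' @param time_per_run_ns production time per run, ns (>= 0).
#' @param n_runs number of runs (>= 1).
#' @return a tibble of class `run_manifest`.
#' @export
manifest <- function(group = character(0), method = character(0),
                     start_note = character(0),
                     time_per_run_ns = numeric(0), n_runs = integer(0)) {
  out <- tibble::tibble(group = as.character(group),
                        method = as.character(method),
                        start_note = as.character(start_note),
                        time_per_run_ns = as.numeric(time_per_run_ns),
                        n_runs = as.integer(n_runs))
  if (nrow(out)) {
    if (any(out$time_per_run_ns < 0) || any(is.na(out$time_per_run_ns))) {
      stop("production times must be >= 0", call. = FALSE)
    }
    if (any(out$n_runs < 1) || any(is.na(out$n_runs))) {
      stop("n_runs must be >= 1", call. = FALSE)
    }
  }
  class(out) <- c("run_manifest", class(out))
  out
}

#' Read / write a manifest as tab-separated text
#'
#' @param path file path.
#' @return [read_manifest()] returns a `run_manifest` tibble;
#'   `write_manifest()` returns `path` invisibly.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group", "method", "start_note", "time_per_run_ns", "n_runs")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("manifest missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  manifest(df$group, df$method, df$start_note, df$time_per_run_ns,
           df$n_runs)
}

#' @rdname read_manifest
#' @param x a `run_manifest` tibble.
#' @export
write_manifest <- function(x, path) {
  stopifnot(inherits(x, "run_manifest"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The bundled Cas9 simulation-campaign ledger
#'
#' The run ledger of the Cas9 HNH-activation simulation campaign whose
#' bookkeeping this package reproduces: conventional, accelerated,
#' targeted and ensemble MD groups G1-G10 with per-run production times
#' and run counts. Groups G1, G2 and G10 are the long conventional-MD
#' sampling runs (11 µs total), G3 and G4 the two accelerated-MD boost
#' levels (3.3 µs total).
#'
#' @return a `run_manifest` tibble.
#' @export
cas9_run_ledger <- function() {
  path <- system.file("extdata", "cas9_run_ledger.tsv", package = "stepmd",
                      mustWork = TRUE)
  read_manifest(path)
}

#' Cumulative production time per method
#'
#' Each row contributes `time_per_run_ns * n_runs`; totals are reported
#' per method plus an overall `(all)` row, in ns and µs.
#'
#' @param x a `run_manifest` (or compatible data frame).
#' @param groups optional group filter; unknown groups raise an error.
#' @param methods optional method filter.
#' @return tibble with `method`, `total_ns`, `total_us` and a
#'   human-readable `label` that switches to µs at 1000 ns.
#' @examples
#' ledger <- manifest(group = c("A", "B"), method = c("cMD", "cMD"),
#'                    start_note = c("", ""),
#'                    time_per_run_ns = c(500, 250), n_runs = c(2, 4))
#' manifest_totals(ledger)
#' @export
manifest_totals <- function(x, groups = NULL, methods = NULL) {
  df <- tibble::as_tibble(x)
  if (!is.null(groups)) {
    unknown <- setdiff(groups, df$group)
    if (length(unknown)) {
      stop("unknown group(s) in filter: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    df <- dplyr::filter(df, .data$group %in% !!groups)
  }
  if (!is.null(methods)) {
    df <- dplyr::filter(df, .data$method %in% !!methods)
  }
  per <- df |>
    dplyr::mutate(row_ns = .data$time_per_run_ns * .data$n_runs) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(total_ns = sum(.data$row_ns), .groups = "drop")
  out <- dplyr::bind_rows(
    per,
    tibble::tibble(method = "(all)", total_ns = sum(per$total_ns))
  )
  out |>
    dplyr::mutate(
      total_us = .data$total_ns / 1000,
      label = ifelse(.data$total_ns >= 1000,
                     sprintf("%g µs", .data$total_us),
                     sprintf("%g ns", .data$total_ns))
    )
}
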