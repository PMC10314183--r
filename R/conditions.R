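#' Assign wells to experimental conditions
#'
#' Builds the condition map used to pool wells into groups. Every well of
#' every monitor receives a label; wells not mentioned in `map_spec` get the
#' default label `"Condition"`. Using the same label on several monitors (or
#' several well ranges) pools those wells into one group.
#'
#' @param map_spec Either `NULL` (all wells get the default label), a data
#'   frame with columns `monitor`, `well`, `condition`, or a list of entries
#'   of the form `list(monitor = 1, wells = 1:6, condition = "wild-type")`.
#' @param monitors Integer vector of monitor ids present in the experiment;
#'   monitors mentioned in `map_spec` are added automatically.
#' @param n_wells Number of wells per monitor (12 on a standard DFM).
#' @param exclude Optional set of wells to mark excluded: a data frame with
#'   columns `monitor`, `well`, or a list of `c(monitor, well)` pairs.
#'   Excluded wells keep their label but are dropped from every downstream
#'   summary (see [exclude_wells()]).
#' @param default Label given to unspecified wells.
#' @return A `flic_conditions` tibble with columns `monitor`, `well`,
#'   `condition`, `excluded`.
#' @export
#' @examples
#' assign_conditions(list(
#'   list(monitor = 1, wells = 1:6, condition = "clk-out"),
#'   list(monitor = 1, wells = 7:12, condition = "w1118")
#' ))
assign_conditions <- function(map_spec = NULL, monitors = 1L, n_wells = 12L,
                              exclude = NULL, default = "Condition") {
  spec <- normalize_map_spec(map_spec)
  if (nrow(spec) > 0) {
    if (any(spec$well < 1 | spec$well > n_wells)) {
      bad <- spec[spec$well < 1 | spec$well > n_wells, ]
      abort(paste0(
        "Well index out of range 1..", n_wells, ": well ",
        paste(unique(bad$well), collapse = ", "), "."
      ))
    }
    dup <- spec |>
      dplyr::distinct(.data$monitor, .data$well, .data$condition) |>
      dplyr::count(.data$monitor, .data$well) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort(paste0(
        "Well assigned to more than one condition: monitor ", dup$monitor[1],
        " well ", dup$well[1], "."
      ))
    }
  }

  all_monitors <- sort(unique(c(as.integer(monitors), spec$monitor)))
  grid <- tidyr::expand_grid(monitor = all_monitors, well = seq_len(n_wells))
  out <- grid |>
    left_join(dplyr::distinct(spec), by = c("monitor", "well")) |>
    mutate(condition = dplyr::coalesce(.data$condition, default),
           excluded = FALSE)

  if (!is.null(exclude)) {
    exc <- normalize_exclude_spec(exclude)
    key <- paste(out$monitor, out$well)
    exc_key <- paste(exc$monitor, exc$well)
    unknown <- setdiff(exc_key, key)
    if (length(unknown) > 0) {
      abort(paste0("Excluded wells are not part of the experiment: ",
                   paste(unknown, collapse = "; "), " (monitor well)."))
    }
    out$excluded <- key %in% exc_key
  }

  structure(out, class = c("flic_conditions", class(tibble())))
}

normalize_map_spec <- function(map_spec) {
  empty <- tibble(monitor = integer(), well = integer(), condition = character())
  if (is.null(map_spec)) return(empty)
  if (is.data.frame(map_spec)) {
    needed <- c("monitor", "well", "condition")
    if (!all(needed %in% names(map_spec))) {
      abort("A data-frame condition map needs columns monitor, well, condition.")
    }
    return(tibble(
      monitor = as.integer(map_spec$monitor),
      well = as.integer(map_spec$well),
      condition = as.character(map_spec$condition)
    ))
  }
  if (is.list(map_spec)) {
    rows <- lapply(map_spec, function(entry) {
      wells <- entry$wells %||% entry$well
      if (is.null(entry$monitor) || is.null(wells) || is.null(entry$condition)) {
        abort("Each condition entry needs `monitor`, `wells` and `condition`.")
      }
      tibble(
        monitor = as.integer(entry$monitor),
        well = as.integer(unlist(wells)),
        condition = as.character(entry$condition)
      )
    })
    return(dplyr::bind_rows(rows))
  }
  abort("`map_spec` must be NULL, a data frame, or a list of entries.")
}

normalize_exclude_spec <- function(exclude) {
  if (is.data.frame(exclude)) {
    return(tibble(monitor = as.integer(exclude$monitor),
                  well = as.integer(exclude$well)))
  }
  if (is.list(exclude)) {
    return(dplyr::bind_rows(lapply(exclude, function(e) {
      if (is.list(e)) {
        tibble(monitor = as.integer(e$monitor), well = as.integer(e$well))
      } else {
        tibble(monitor = as.integer(e[1]), well = as.integer(e[2]))
      }
    })))
  }
  abort("`exclude` must be a data frame or a list of (monitor, well) pairs.")
}
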