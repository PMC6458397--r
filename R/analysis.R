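# Trace summaries and export ---------------------------------------------

#' Summarise per-replicate traces into mean learning curves
#'
#' Collapses a long table of per-replicate traced values (as attached by
#' \code{run_replicates(..., keep_replicates = TRUE)}) into per-trial means
#' and standard errors across replicates. The result is invariant under
#' permutation of replicate labels.
#'
#' @param replicates A data frame with columns \code{arm},
#'   \code{replicate}, \code{trial_index}, \code{quantity}, \code{value};
#'   every replicate of an arm must cover the same trial indices.
#' @return A \code{learning_traces} tibble with columns \code{arm},
#'   \code{trial_index}, \code{quantity}, \code{mean}, \code{stderr},
#'   \code{n_replicates}.
#' @examples
#' reps <- tibble::tibble(
#'   arm = "a", replicate = rep(1:2, each = 2), trial_index = rep(0:1, 2),
#'   quantity = "v:X->B", value = c(2, 2, 4, 4)
#' )
#' summarize_traces(reps)
#' @export
summarize_traces <- function(replicates) {
  replicates <- tibble::as_tibble(replicates)
  needed <- c("arm", "replicate", "trial_index", "quantity", "value")
  missing_cols <- setdiff(needed, names(replicates))
  if (length(missing_cols)) {
    stop("`replicates` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(replicates) == 0L) stop("no replicates to summarise", call. = FALSE)
  counts <- replicates |>
    dplyr::distinct(.data$arm, .data$replicate, .data$trial_index) |>
    dplyr::count(.data$arm, .data$replicate, name = "n_trials") |>
    dplyr::distinct(.data$arm, .data$n_trials)
  if (anyDuplicated(counts$arm)) {
    stop("replicates have ragged trial counts within an arm", call. = FALSE)
  }
  out <- replicates |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$arm, .data$trial_index, .data$quantity) |>
    dplyr::summarise(
      mean = mean(.data$value),
      stderr = if (dplyr::n() > 1) {
        stats::sd(.data$value) / sqrt(dplyr::n())
      } else {
        0
      },
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  new_learning_traces(out)
}

#' Write learning traces to CSV
#'
#' Deterministic layout: header
#' \code{arm,trial_index,quantity,mean,stderr,n_replicates}, rows ordered by
#' (arm, quantity, trial), numeric fields printed to 12 significant digits
#' so a written table re-reads to the same values at that precision.
#'
#' @param table A \code{learning_traces} tibble (or compatible data frame).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(table, path) {
  cols <- c("arm", "trial_index", "quantity", "mean", "stderr", "n_replicates")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop("trace table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  tbl <- dplyr::arrange(tibble::as_tibble(table)[cols],
                        .data$arm, .data$quantity, .data$trial_index)
  lines <- c(
    paste(cols, collapse = ","),
    if (nrow(tbl)) {
      paste(
        tbl$arm, tbl$trial_index, tbl$quantity,
        formatC(tbl$mean, digits = 12, format = "g"),
        formatC(tbl$stderr, digits = 12, format = "g"),
        tbl$n_replicates,
        sep = ","
      )
    }
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read learning traces from CSV
#'
#' @param path A file written by \code{\link{write_trace_csv}}.
#' @return A \code{learning_traces} tibble.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(
                          arm = "character", trial_index = "integer",
                          quantity = "character", mean = "numeric",
                          stderr = "numeric", n_replicates = "integer"
                        ))
  new_learning_traces(tibble::as_tibble(df))
}

# Plotting ----------------------------------------------------------------

trace_panel <- function(quantity) {
  ifelse(grepl("^(p[:_]|p_|freq:|p:)", quantity),
         "response probability", "memory values")
}

#' Plot learning traces
#'
#' Two-panel figure in the style of the scenario figures: response
#' probabilities in one panel, underlying memory values (v and w) in the
#' other, one curve per quantity, line type by arm.
#'
#' @param object A \code{learning_traces} tibble.
#' @param ribbon Draw a +/- 2 standard error ribbon.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.learning_traces <- function(object, ribbon = TRUE, ...) {
  df <- tibble::as_tibble(object)
  df$panel <- trace_panel(df$quantity)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$trial_index, y = .data$mean,
    colour = .data$quantity, linetype = .data$arm
  ))
  if (ribbon) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - 2 * .data$stderr,
                   ymax = .data$mean + 2 * .data$stderr,
                   fill = .data$quantity),
      alpha = 0.15, colour = NA, show.legend = FALSE
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "learning opportunities", y = NULL,
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Save a learning-trace figure to file
#'
#' Best-effort rendering of \code{\link{autoplot.learning_traces}}; never
#' affects numeric outputs. An empty table produces a warning and no file.
#'
#' @param table A \code{learning_traces} tibble.
#' @param path Image path (extension picks the device, e.g. .png, .pdf).
#' @param width,height,dpi Passed to \code{ggplot2::ggsave}.
#' @return \code{path} invisibly, or \code{NULL} if nothing was plotted.
#' @export
plot_traces <- function(table, path, width = 8, height = 4, dpi = 150) {
  if (nrow(table) == 0L) {
    warning("empty trace table: no figure written")
    return(invisible(NULL))
  }
  p <- autoplot.learning_traces(table)
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = dpi)
  invisible(path)
}

# broom-style methods ------------------------------------------------------

#' @export
tidy.learning_traces <- function(x, ...) tibble::as_tibble(x)

#' Final-trial summary of learning traces
#'
#' One row per arm: the mean of every traced quantity at the last recorded
#' trial, in wide form, plus the trial index and replicate count.
#'
#' @param x A \code{learning_traces} tibble.
#' @param ... Unused.
#' @return A wide tibble with one row per arm.
#' @export
glance.learning_traces <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$arm) |>
    dplyr::filter(.data$trial_index == max(.data$trial_index)) |>
    dplyr::ungroup() |>
    dplyr::select("arm", "trial_index", "n_replicates", "quantity", "mean") |>
    tidyr::pivot_wider(names_from = "quantity", values_from = "mean")
}
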