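#' Learning parameters
#'
#' Bundles the three free parameters of the learning model: the
#' stimulus-response learning rate \code{alpha_v}, the stimulus-value
#' (conditioned reinforcement) learning rate \code{alpha_w}, and the softmax
#' exploration parameter \code{beta}. Defaults are the values used throughout
#' the built-in scenarios. Setting \code{alpha_w = 0} disables Pavlovian
#' stimulus-value learning; \code{beta = 0} makes all behaviours equally
#' likely regardless of learned values.
#'
#' @param alpha_v Stimulus-response learning rate, in (0, 1].
#' @param alpha_w Stimulus-value learning rate, in [0, 1].
#' @param beta Exploration parameter, >= 0. Larger values exploit learned
#'   values more greedily.
#' @return A list of class \code{learning_parameters}.
#' @examples
#' learning_parameters()
#' learning_parameters(alpha_w = 0) # instrumental learning only
#' @export
learning_parameters <- function(alpha_v = 0.1, alpha_w = 0.1, beta = 1) {
  stopifnot(
    is.numeric(alpha_v), length(alpha_v) == 1L, is.finite(alpha_v),
    alpha_v > 0, alpha_v <= 1,
    is.numeric(alpha_w), length(alpha_w) == 1L, is.finite(alpha_w),
    alpha_w >= 0, alpha_w <= 1,
    is.numeric(beta), length(beta) == 1L, is.finite(beta), beta >= 0
  )
  structure(
    list(alpha_v = as.double(alpha_v), alpha_w = as.double(alpha_w),
         beta = as.double(beta)),
    class = "learning_parameters"
  )
}

#' Agent memory
#'
#' The learner's state: a table \code{v} of stimulus-response values (one row
#' per stimulus element, one column per behaviour), a vector \code{w} of
#' learned stimulus values, the innate reinforcement values \code{u} of the
#' stimulus elements, and the learning parameters. All values start at zero
#' unless priors are supplied; missing priors read as zero.
#'
#' @param u Named numeric vector of innate reinforcement values, one per
#'   stimulus element. Names are the element identifiers. Values may be
#'   negative (e.g. a warning call), zero, or positive (a reward).
#' @param repertoire Character vector of behaviour names (at least two,
#'   including any designated "other/ignore" behaviour, which is an ordinary
#'   behaviour).
#' @param params A \code{\link{learning_parameters}} object.
#' @param v_prior Optional data frame with columns \code{element},
#'   \code{behaviour}, \code{value} giving non-zero initial v entries.
#' @param w_prior Optional named numeric vector of initial w values.
#' @param is_social Optional named logical vector flagging which elements are
#'   social. Metadata only: learning treats social and non-social elements
#'   identically.
#' @return An object of class \code{agent_memory}.
#' @examples
#' mem <- agent_memory(
#'   u = c(S_social = 0, S_reward = 25, S_no_reward = 0),
#'   repertoire = c("B", "other"),
#'   params = learning_parameters(alpha_w = 0)
#' )
#' mem
#' @export
agent_memory <- function(u, repertoire, params = learning_parameters(),
                         v_prior = NULL, w_prior = NULL, is_social = NULL) {
  if (is.null(names(u)) || anyDuplicated(names(u)) || any(!nzchar(names(u)))) {
    stop("`u` must be a named numeric vector with unique, non-empty names",
         call. = FALSE)
  }
  if (!all(is.finite(u))) stop("innate values `u` must be finite", call. = FALSE)
  repertoire <- as.character(repertoire)
  if (length(repertoire) < 2L || anyDuplicated(repertoire)) {
    stop("`repertoire` must hold at least two distinct behaviour names",
         call. = FALSE)
  }
  stopifnot(inherits(params, "learning_parameters"))
  elements <- names(u)
  v <- matrix(0, nrow = length(elements), ncol = length(repertoire),
              dimnames = list(elements, repertoire))
  w <- stats::setNames(numeric(length(elements)), elements)
  if (!is.null(v_prior)) {
    v_prior <- as.data.frame(v_prior)
    stopifnot(all(c("element", "behaviour", "value") %in% names(v_prior)))
    check_elements(v_prior$element, elements)
    check_behaviours(v_prior$behaviour, repertoire)
    for (i in seq_len(nrow(v_prior))) {
      v[v_prior$element[i], v_prior$behaviour[i]] <- v_prior$value[i]
    }
  }
  if (!is.null(w_prior)) {
    check_elements(names(w_prior), elements)
    w[names(w_prior)] <- w_prior
  }
  social <- stats::setNames(logical(length(elements)), elements)
  if (!is.null(is_social)) {
    check_elements(names(is_social), elements)
    social[names(is_social)] <- is_social
  }
  structure(
    list(
      u = u, v = v, w = w,
      repertoire = repertoire, is_social = social,
      alpha_v = params$alpha_v, alpha_w = params$alpha_w, beta = params$beta
    ),
    class = "agent_memory"
  )
}

#' @export
print.agent_memory <- function(x, ...) {
  cat("<agent_memory>: ", length(x$u), " elements x ", length(x$repertoire),
      " behaviours (alpha_v = ", x$alpha_v, ", alpha_w = ", x$alpha_w,
      ", beta = ", x$beta, ")\n", sep = "")
  cat("v:\n")
  print(x$v)
  cat("w:\n")
  print(x$w)
  invisible(x)
}

#' Tidy an agent memory into a long table
#'
#' Flattens the memory into one row per stored value: v entries carry both an
#' element and a behaviour, w and u entries only an element.
#'
#' @param x An \code{\link{agent_memory}}.
#' @param ... Unused.
#' @return A tibble with columns \code{type} ("v", "w" or "u"),
#'   \code{element}, \code{behaviour} (NA for w/u rows) and \code{value}.
#' @export
tidy.agent_memory <- function(x, ...) {
  v_tbl <- tibble::tibble(
    type = "v",
    element = rep(rownames(x$v), times = ncol(x$v)),
    behaviour = rep(colnames(x$v), each = nrow(x$v)),
    value = as.vector(x$v)
  )
  w_tbl <- tibble::tibble(type = "w", element = names(x$w),
                          behaviour = NA_character_, value = unname(x$w))
  u_tbl <- tibble::tibble(type = "u", element = names(x$u),
                          behaviour = NA_character_, value = unname(x$u))
  dplyr::arrange(dplyr::bind_rows(v_tbl, w_tbl, u_tbl),
                 .data$type, .data$element, .data$behaviour)
}

# name validation helpers -------------------------------------------------

check_elements <- function(x, known) {
  bad <- setdiff(unique(x), known)
  if (length(bad)) {
    stop("unknown stimulus element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

check_behaviours <- function(x, repertoire) {
  bad <- setdiff(unique(x), repertoire)
  if (length(bad)) {
    stop("unknown behaviour(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

check_compound <- function(stimulus, known) {
  stimulus <- as.character(stimulus)
  if (length(stimulus) == 0L) stop("a compound stimulus must be non-empty", call. = FALSE)
  if (anyDuplicated(stimulus)) {
    stop("a compound stimulus cannot repeat an element", call. = FALSE)
  }
  check_elements(stimulus, known)
  stimulus
}
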