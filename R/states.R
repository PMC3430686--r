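#' @keywords internal
"_PACKAGE"

# Joint states of the dyad:
#   1 = both under cover, 2 = focal out / partner under,
#   3 = partner out / focal under, 4 = both out.
# Only one fish moves per event, so 1<->4 and 2<->3 are structural zeros.

#' Permitted transition edges of the four-state dyad chain
#'
#' The eight single-fish-move transitions, encoded as two-character strings
#' `"ij"` (from state `i` to state `j`).  Transitions `1<->4` and `2<->3`
#' would require both fish to move at the same instant and are structural
#' zeros.
#'
#' @format Character vector of length 8.
#' @export
EDGES <- c("12", "21", "13", "31", "24", "42", "34", "43")

STATES <- 1:4

edge_key <- function(from, to) paste0(from, to)
edge_from <- function(edge) as.integer(substr(edge, 1, 1))
edge_to <- function(edge) as.integer(substr(edge, 2, 2))

#' Is a (from, to) transition a permitted single-fish move?
#'
#' @param from,to Integer state labels in 1..4.
#' @return Logical vector.
#' @export
is_permitted_edge <- function(from, to) {
  edge_key(from, to) %in% EDGES
}

#' State predicates: which fish is out of cover in a given state
#'
#' @param state Integer state label(s) in 1..4.
#' @return Logical vector.
#' @export
focal_is_out <- function(state) state %in% c(2L, 4L)

#' @rdname focal_is_out
#' @export
partner_is_out <- function(state) state %in% c(3L, 4L)

# Which fish moves on a given permitted edge, and in which direction.
# Focal edges: 12, 21, 34, 43.  Partner edges: 13, 31, 24, 42.
edge_actor <- function(edge) {
  ifelse(edge %in% c("12", "21", "34", "43"), "focal", "partner")
}

# TRUE if the edge is the actor leaving cover (as opposed to returning).
edge_is_leave <- function(edge) edge %in% c("12", "13", "24", "34")

assert_state <- function(x, what = "state") {
  x <- as.integer(x)
  if (any(is.na(x)) || any(!x %in% STATES)) {
    stop(sprintf("%s must be an integer in 1..4", what), call. = FALSE)
  }
  x
}
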