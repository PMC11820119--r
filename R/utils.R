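#' Round half-up (half away from zero)
#'
#' Decimal rounding in which a value exactly halfway between two neighbours is
#' rounded away from zero, the convention used when food composition tables are
#' published to a fixed number of decimals. This differs from [base::round()],
#' which rounds half to even. A guard of `sqrt(.Machine$double.eps)` absorbs
#' binary representation error in inputs such as `0.185`, so inputs within
#' ~1.5e-8 of a half-way point round upward.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2, the export convention).
#' @return numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(0.185)      # 0.19, where round(0.185, 2) gives 0.18
#' round_half_up(16.684999)  # 16.68
#' round_half_up(-0.185)     # -0.19 (away from zero)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' @noRd
`%||%` <- rlang::`%||%`

abort_validation <- function(msg, ..., class = character()) {
  rlang::abort(msg, ..., class = c(class, "gwpstar_validation_error"))
}

abort_cycle <- function(cycle, what = "recipe") {
  rlang::abort(
    sprintf("Cycle detected in %s graph: %s", what,
            paste(c(cycle, cycle[[1]]), collapse = " -> ")),
    class = c("gwpstar_cycle_error", "gwpstar_validation_error"),
    cycle = cycle
  )
}

#' Topologically order a dependency graph, or fail with the cycle path
#'
#' Iterative depth-first search over edges `from -> to`, where `from` depends
#' on `to` (a parent food depends on its ingredients). Returns node ids in
#' dependency order: every node appears after all nodes it depends on. A cycle
#' raises a classed condition (`gwpstar_cycle_error`) whose `cycle` field holds
#' the offending path, so callers never loop forever on malformed input.
#'
#' @param edges data frame with character columns `from` and `to`.
#' @param nodes optional character vector of node ids to include even when
#'   isolated (no incident edges).
#' @param what label used in the cycle error message (e.g. `"recipe"`).
#' @return character vector of node ids, dependencies first.
#' @keywords internal
topo_order <- function(edges, nodes = NULL, what = "recipe") {
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  all_nodes <- unique(c(nodes, from, to))
  adj <- split(to, factor(from, levels = all_nodes))

  state <- stats::setNames(integer(length(all_nodes)), all_nodes) # 0 new, 1 open, 2 done
  order_out <- character(0)

  for (root in all_nodes) {
    if (state[[root]] != 0L) next
    # explicit stack of (node, next-child index) to avoid deep recursion
    stack <- list(list(node = root, i = 1L))
    state[[root]] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      kids <- adj[[top$node]]
      if (is.null(kids) || top$i > length(kids)) {
        state[[top$node]] <- 2L
        order_out <- c(order_out, top$node)
        stack[[length(stack)]] <- NULL
        next
      }
      child <- kids[[top$i]]
      stack[[length(stack)]]$i <- top$i + 1L
      if (state[[child]] == 1L) {
        path <- vapply(stack, `[[`, character(1), "node")
        cycle <- c(path[which(path == child)[1]:length(path)])
        abort_cycle(cycle, what = what)
      }
      if (state[[child]] == 0L) {
        state[[child]] <- 1L
        stack[[length(stack) + 1L]] <- list(node = child, i = 1L)
      }
    }
  }
  order_out
}

# Format a numeric value for export: fixed decimals, empty string for NA.
format_export <- function(x, digits = 2) {
  out <- ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), round_half_up(x, digits)))
  as.character(out)
}
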