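#' Define a tunnel network of landmark residue groups
#'
#' A tunnel network is the landmark definition every downstream stage relies
#' on: a catalytic residue group whose centre of mass (COM) anchors the bottom
#' of the active-site cavity, and one bottleneck residue group per transport
#' tunnel. The order in which tunnels are given is their canonical order and
#' is used to break ties deterministically when the ligand is equidistant from
#' two bottlenecks.
#'
#' @param catalytic character vector of residue identifiers forming the
#'   catalytic machinery (e.g. `c("N38", "D108", "W109")`).
#' @param tunnels named list; each element a character vector of bottleneck
#'   residue identifiers for that tunnel (e.g.
#'   `list(p2 = c("L211", "L248"))`). Names must be unique.
#' @return An object of class `tunnel_network`.
#' @examples
#' tunnel_network(
#'   catalytic = c("N38", "D108", "W109"),
#'   tunnels = list(
#'     p1a = c("D147", "F151", "V173"),
#'     p1b = c("D147", "W177", "L248"),
#'     p2  = c("L211", "L248"),
#'     p3  = c("L143", "F151", "I213")
#'   )
#' )
#' @export
tunnel_network <- function(catalytic, tunnels) {
  if (length(catalytic) < 1L) stop("empty landmark group: catalytic")
  if (!is.list(tunnels) || length(tunnels) < 1L)
    stop("a tunnel network needs at least one tunnel")
  ids <- names(tunnels)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("tunnel ids must be unique non-empty names")
  for (id in ids) {
    if (length(tunnels[[id]]) < 1L)
      stop("empty landmark group: tunnel ", id)
  }
  structure(
    list(catalytic = as.character(catalytic),
         tunnels = lapply(tunnels, as.character)),
    class = "tunnel_network"
  )
}

#' @export
print.tunnel_network <- function(x, ...) {
  cat("Tunnel network:", length(x$tunnels), "tunnel(s)\n")
  cat("  catalytic:", paste(x$catalytic, collapse = ", "), "\n")
  for (id in names(x$tunnels))
    cat("  ", id, ": ", paste(x$tunnels[[id]], collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

tunnel_ids <- function(net) names(net$tunnels)
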