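# Cubed-sphere spherical shell mesh, used for closed-form solver
# verification (thick-walled pressurised sphere).

#' Mesh a closed thick-walled spherical shell
#'
#' Cubed-sphere topology: six structured panels of `n x n` quads projected
#' onto the sphere, extruded radially in `layers` element layers from the
#' inner to the outer radius.
#'
#' @param inner,outer shell radii, mm
#' @param n panel resolution (n x n quads per cube face)
#' @param layers radial element layers
#' @return a `hex_mesh` with facet sets `inner_wall`, `outer_wall`
#' @export
mesh_spherical_shell <- function(inner = 11.5, outer = 12.05, n = 10L, layers = 3L) {
  stopifnot(outer > inner, n >= 2, layers >= 1)
  u <- seq(-1, 1, length.out = n + 1L)
  faces <- list(
    function(a, b) cbind(1, a, b),
    function(a, b) cbind(-1, -a, b),
    function(a, b) cbind(-a, 1, b),
    function(a, b) cbind(a, -1, b),
    function(a, b) cbind(b, a, 1),
    function(a, b) cbind(-b, a, -1)
  )
  # gather unique direction nodes across panels (shared edges merged)
  dir_list <- list()
  key_map <- new.env(hash = TRUE)
  panel_ids <- vector("list", 6L)
  nid <- 0L
  for (f in seq_along(faces)) {
    A <- outer(u, rep(1, n + 1L))
    B <- outer(rep(1, n + 1L), u)
    P <- faces[[f]](as.vector(A), as.vector(B))
    D <- P / sqrt(rowSums(P^2))
    ids <- integer(nrow(D))
    for (i in seq_len(nrow(D))) {
      k <- paste(round(D[i, ] * 1e9), collapse = ",")
      hit <- key_map[[k]]
      if (is.null(hit)) {
        nid <- nid + 1L
        key_map[[k]] <- nid
        dir_list[[nid]] <- D[i, ]
        ids[i] <- nid
      } else {
        ids[i] <- hit
      }
    }
    panel_ids[[f]] <- matrix(ids, n + 1L, n + 1L)
  }
  dirs <- do.call(rbind, dir_list)
  n_dir <- nrow(dirs)
  quads <- do.call(rbind, lapply(panel_ids, function(pid) {
    out <- matrix(0L, n * n, 4L)
    q <- 0L
    for (j in seq_len(n)) {
      for (i in seq_len(n)) {
        q <- q + 1L
        out[q, ] <- c(pid[i, j], pid[i + 1L, j], pid[i + 1L, j + 1L], pid[i, j + 1L])
      }
    }
    out
  }))
  radii <- seq(inner, outer, length.out = layers + 1L)
  nodes <- do.call(rbind, lapply(radii, function(r) dirs * r))
  elems <- stack_sheets_to_hex(quads, n_dir, layers)
  # orient each panel's quads so extrusion (inner -> outer) is positive
  detj <- hex8_min_detj(nodes, elems)
  flip <- detj <= 0
  if (any(flip)) {
    elems[flip, ] <- elems[flip, c(4, 3, 2, 1, 8, 7, 6, 5)]
  }
  base_quads <- elems[seq_len(nrow(quads)), 1:4, drop = FALSE]
  inner_f <- base_quads[, c(1, 4, 3, 2)]
  outer_f <- elems[(layers - 1L) * nrow(quads) + seq_len(nrow(quads)), 5:8, drop = FALSE]
  mesh <- hex_mesh(
    nodes = nodes, elems = elems,
    facets = list(inner_wall = inner_f, outer_wall = outer_f),
    meta = list(component = "shell", inner = inner, outer = outer)
  )
  stopifnot(all(hex8_min_detj(mesh$nodes, mesh$elems) > 0))
  mesh
}
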