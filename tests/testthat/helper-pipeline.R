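# Shared, lazily computed pipeline fixtures. The demonstration pipeline is
# expensive (SDF voxelization of the whole splint), so tests that need its
# stages share one cached run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(build)
  .fixture_cache[[name]]
}

demo_limb <- function() {
  fixture("limb", generate_limb(limb_preset("wrist_default", seed = 1L)))
}

demo_shell <- function() {
  fixture("shell", {
    off <- offset_surface(demo_limb(), 2)
    apply_cut_planes(off, list(
      cut_plane(c(0, 0, 55), c(0, 0, 1), "positive"),
      cut_plane(c(0, 0, 195), c(0, 0, 1), "negative")))
  })
}

demo_draft <- function() {
  fixture("draft", remesh_isotropic(demo_shell(), remesh_params(12)))
}

demo_run <- function() {
  fixture("run", {
    out <- file.path(tempdir(), "splintfab-demo-run")
    suppressMessages(run_pipeline(demo_config(seed = 1L), out, quiet = TRUE))
  })
}

# a long strut whose midpoint is well clear of every other strut centerline,
# so its cross-section is an isolated loop
well_separated_strut <- function(lattice) {
  len <- lattice_edge_lengths(lattice)
  cand <- order(len, decreasing = TRUE)[1:20]
  best <- NULL
  best_clear <- -Inf
  for (k in cand) {
    e <- lattice$edges[k, ]
    mid <- (lattice$nodes[e[1], ] + lattice$nodes[e[2], ]) / 2
    clear <- Inf
    for (j in seq_len(nrow(lattice$edges))) {
      if (j == k) next
      p <- lattice$nodes[lattice$edges[j, 1], ]
      q <- lattice$nodes[lattice$edges[j, 2], ]
      u <- q - p
      t <- max(0, min(1, sum((mid - p) * u) / sum(u * u)))
      clear <- min(clear, sqrt(sum((p + t * u - mid)^2)))
    }
    if (clear > best_clear) {
      best_clear <- clear
      best <- k
    }
  }
  e <- lattice$edges[best, ]
  list(edge = best,
       mid = (lattice$nodes[e[1], ] + lattice$nodes[e[2], ]) / 2,
       axis = lattice$nodes[e[2], ] - lattice$nodes[e[1], ],
       length = len[best], clearance = best_clear)
}
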