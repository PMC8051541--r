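# Independent volume measurement by z-column ray casting: used to
# cross-check the divergence-theorem mesh volume and the SDF union path.

#' Ray-cast volume of a closed mesh
#'
#' Integrates inside-segment lengths along a grid of z-parallel rays. This
#' path shares no code with [mesh_volume()] (divergence theorem) or with
#' the SDF solidification, so the three can cross-validate each other.
#'
#' @param mesh a closed [surface_mesh()].
#' @param pitch ray spacing in mm.
#' @return volume in mm^3.
#' @export
voxel_volume <- function(mesh, pitch = 0.5) {
  cpp_raycast_volume(mesh$vertices, mesh$faces, pitch)
}

#' Ray-cast volume of the union of two closed meshes
#'
#' @param mesh1,mesh2 closed [surface_mesh()]es.
#' @param pitch ray spacing in mm.
#' @return union volume in mm^3.
#' @export
union_volume <- function(mesh1, mesh2, pitch = 0.5) {
  cpp_union_volume(mesh1$vertices, mesh1$faces,
                   mesh2$vertices, mesh2$faces, pitch)
}
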