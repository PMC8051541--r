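# End-to-end orchestration: one config drives generate/read -> offset ->
# cut -> remesh -> optimize -> solidify -> blocks -> split -> export, with
# per-stage logging and resumability from the OBJ/STL hand-off artifacts.

#' Assemble and validate a pipeline configuration
#'
#' The bar radius ties the two key numbers together: the offset distance
#' must equal half the strut diameter (the strut centerlines live on the
#' offset surface), unless `allow_offset_mismatch` is set.
#'
#' @param input list: either `preset` (a [limb_preset()] name) or `path`
#'   to an STL/OBJ scan.
#' @param offset_distance_mm offset of the shell above the skin (mm).
#' @param cut_planes list of plain lists with `point`, `normal`, `keep`.
#' @param remesh list: `target_edge_mm`, `iterations`, `smoothing_weight`.
#' @param optimizer list of [optimizer_params()] arguments.
#' @param strut list: `diameter_mm`, `union_method`, `voxel_pitch_mm`
#'   (`NULL` for diameter/8).
#' @param blocks list: either `auto = TRUE` with `stations` (fractions of
#'   the shell length) and `hole_dir`, or explicit `anchors` (each a list
#'   with `anchor`, `normal`); plus `dims` and `hole_diameter_mm`.
#' @param split_plane plain list with `point`, `normal`, `keep`.
#' @param seed integer seed for the synthetic limb.
#' @param allow_offset_mismatch permit offset != strut radius.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = list(preset = "wrist_default"),
                            offset_distance_mm = 2,
                            cut_planes = list(),
                            remesh = list(target_edge_mm = 12,
                                          iterations = 10L,
                                          smoothing_weight = 0.5),
                            optimizer = list(),
                            strut = list(diameter_mm = 4,
                                         union_method = "sdf_voxel",
                                         voxel_pitch_mm = NULL),
                            blocks = list(auto = TRUE,
                                          stations = c(0.2, 0.5, 0.8),
                                          hole_dir = c(0, 1, 0),
                                          dims = c(20, 12, 8),
                                          hole_diameter_mm = 4),
                            split_plane = list(point = c(0, 0, 0),
                                               normal = c(0, 1, 0),
                                               keep = "positive"),
                            seed = 1L,
                            allow_offset_mismatch = FALSE) {
  cfg <- list(input = input, offset_distance_mm = offset_distance_mm,
              cut_planes = cut_planes, remesh = remesh,
              optimizer = optimizer, strut = strut, blocks = blocks,
              split_plane = split_plane, seed = as.integer(seed),
              allow_offset_mismatch = isTRUE(allow_offset_mismatch))
  if (is.null(cfg$strut$diameter_mm)) cfg$strut$diameter_mm <- 4
  if (!cfg$allow_offset_mismatch &&
      abs(cfg$offset_distance_mm - cfg$strut$diameter_mm / 2) > 1e-9)
    stop("offset_distance_mm must equal strut diameter / 2 (the bar ",
         "radius); set allow_offset_mismatch = TRUE to override")
  if (cfg$offset_distance_mm <= 0) stop("offset_distance_mm must be > 0")
  structure(cfg, class = "pipeline_config")
}

#' The demonstration wrist preset
#'
#' Encodes the canonical wrist-splint parameters: 2 mm offset (bar radius), 4 mm
#' strut diameter, six fastening blocks in three stations on both lateral
#' sides, and one split plane through the limb axis.
#'
#' @param seed synthetic-limb seed.
#' @return a [pipeline_config()].
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(
    input = list(preset = "wrist_default"),
    offset_distance_mm = 2,
    cut_planes = list(
      list(point = c(0, 0, 55), normal = c(0, 0, 1), keep = "positive"),
      list(point = c(0, 0, 195), normal = c(0, 0, 1), keep = "negative")),
    remesh = list(target_edge_mm = 12, iterations = 10L,
                  smoothing_weight = 0.5),
    optimizer = list(),
    strut = list(diameter_mm = 4, union_method = "sdf_voxel",
                 voxel_pitch_mm = NULL),
    blocks = list(auto = TRUE, stations = c(0.2, 0.5, 0.8),
                  hole_dir = c(0, 1, 0), dims = c(20, 12, 8),
                  hole_diameter_mm = 4),
    split_plane = list(point = c(0, 0, 0), normal = c(0, 1, 0),
                       keep = "positive"),
    seed = seed)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with keys matching [pipeline_config()] arguments.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

as_cut_plane <- function(pl) {
  cut_plane(unlist(pl$point), unlist(pl$normal),
            if (is.null(pl$keep)) "positive" else pl$keep)
}

# small rolling hash so reports can assert which config produced them
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  m <- 2^31 - 1
  for (b in bytes) h <- (h * 33 + b) %% m
  sprintf("%08x", as.integer(h))
}

#' Compute block poses on the optimized shell
#'
#' With `auto = TRUE` the anchors are placed at the given axial stations on
#' both lateral extremes of the shell (the widest points, where the split
#' seam runs), which yields the classic clamshell bolt layout.
#'
#' @param shell the optimized shell mesh.
#' @param blocks_cfg the `blocks` entry of a [pipeline_config()].
#' @return list of [block_spec()]s.
#' @export
plan_blocks <- function(shell, blocks_cfg) {
  dims <- unlist(blocks_cfg$dims)
  hole <- blocks_cfg$hole_diameter_mm
  hole_dir <- unlist(blocks_cfg$hole_dir)
  anchors <- list()
  if (isTRUE(blocks_cfg$auto)) {
    v <- shell$vertices
    zr <- range(v[, 3])
    for (fz in unlist(blocks_cfg$stations)) {
      zs <- zr[1] + fz * diff(zr)
      near <- which(abs(v[, 3] - zs) < 6)
      if (length(near) == 0L) next
      ip <- near[which.max(v[near, 1])]
      im <- near[which.min(v[near, 1])]
      anchors[[length(anchors) + 1L]] <-
        list(anchor = v[ip, ], normal = c(1, 0, 0))
      anchors[[length(anchors) + 1L]] <-
        list(anchor = v[im, ], normal = c(-1, 0, 0))
    }
  } else {
    anchors <- blocks_cfg$anchors
  }
  lapply(anchors, function(a)
    block_from_anchor(unlist(a$anchor), unlist(a$normal), hole_dir,
                      dims = dims, hole_diameter = hole))
}

#' Run the full splint pipeline
#'
#' Executes generate/read, offset, cuts, remesh, optimize, solidify, block
#' attachment, split and export. Writes `draft_shell.obj`,
#' `optimized_shell.obj`, `splint_solid.stl`, `piece_top.stl`,
#' `piece_bottom.stl` and `report.json` into `output_dir`.
#'
#' @param config a [pipeline_config()].
#' @param output_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return a `splint_run_report` (invisibly contains all artifacts' paths
#'   and statistics).
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(config), config_hash = config_hash(config),
                 stages = list(), artifacts = list(), validation = list())
  say <- function(...) if (!quiet) message(sprintf(...))
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    report$stages[[name]] <<- list(seconds = proc.time()[["elapsed"]] - t0)
    out
  }

  limb <- timed("input", {
    if (!is.null(config$input$path)) {
      read_mesh(config$input$path)
    } else {
      generate_limb(limb_preset(config$input$preset, seed = config$seed))
    }
  })
  say("input: %d vertices, %d faces", nrow(limb$vertices), nrow(limb$faces))

  shell <- timed("offset", offset_surface(limb, config$offset_distance_mm))
  shell <- timed("cut", {
    planes <- lapply(config$cut_planes, as_cut_plane)
    apply_cut_planes(shell, planes)
  })
  draft <- timed("remesh", {
    rp <- remesh_params(config$remesh$target_edge_mm,
                        iterations = config$remesh$iterations,
                        smoothing_weight = config$remesh$smoothing_weight)
    remesh_isotropic(shell, rp)
  })
  say("draft shell: %d vertices, %d faces", nrow(draft$vertices),
      nrow(draft$faces))
  draft_path <- file.path(output_dir, "draft_shell.obj")
  write_mesh(draft, draft_path)
  report$artifacts$draft_shell <- draft_path

  opt_params <- do.call(optimizer_params, config$optimizer)
  lattice <- extract_lattice(draft)
  opt <- timed("optimize", optimize_lattice(lattice, draft, opt_params))
  report$optimizer <- list(
    iterations = attr(opt, "iterations"),
    converged = attr(opt, "converged"),
    quality_initial = unclass(attr(opt, "quality_initial")),
    quality_final = unclass(attr(opt, "quality_final")))
  say("optimizer: %d iterations (converged: %s)",
      attr(opt, "iterations"), attr(opt, "converged"))
  opt_shell <- surface_mesh(opt$nodes, draft$faces)
  opt_path <- file.path(output_dir, "optimized_shell.obj")
  write_mesh(opt_shell, opt_path)
  report$artifacts$optimized_shell <- opt_path

  sp <- strut_params(config$strut$diameter_mm,
                     method = config$strut$union_method,
                     voxel_pitch = if (is.null(config$strut$voxel_pitch_mm))
                       config$strut$diameter_mm / 8
                     else config$strut$voxel_pitch_mm)
  solid <- timed("solidify", strut_solid(opt, sp))
  blocks <- plan_blocks(opt_shell, config$blocks)
  solid <- timed("blocks", attach_blocks(solid, blocks))
  report$n_blocks <- length(blocks)
  solid_path <- file.path(output_dir, "splint_solid.stl")
  write_mesh(solid, solid_path)
  report$artifacts$solid <- solid_path
  report$validation$solid <-
    unclass(validate_mesh(solid, expect_closed = TRUE,
                          check_intersections = FALSE))[
      c("watertight", "consistent_winding", "n_boundary_loops",
        "n_nonmanifold_edges", "volume")]

  pieces <- timed("split", split_solid(solid, as_cut_plane(config$split_plane)))
  top_path <- file.path(output_dir, "piece_top.stl")
  bottom_path <- file.path(output_dir, "piece_bottom.stl")
  write_mesh(pieces$first, top_path)
  write_mesh(pieces$second, bottom_path)
  report$artifacts$piece_top <- top_path
  report$artifacts$piece_bottom <- bottom_path
  for (nm in c("piece_top", "piece_bottom")) {
    piece <- if (nm == "piece_top") pieces$first else pieces$second
    report$validation[[nm]] <-
      unclass(validate_mesh(piece, expect_closed = TRUE,
                            check_intersections = FALSE))[
        c("watertight", "consistent_winding", "n_boundary_loops",
          "n_nonmanifold_edges", "volume")]
  }
  report$blocks <- blocks
  report$limb <- limb
  report$draft <- draft
  report$optimized <- opt
  report$solid <- solid
  report$pieces <- pieces

  rp_path <- file.path(output_dir, "report.json")
  writable <- report[c("config", "config_hash", "stages", "artifacts",
                       "validation", "optimizer", "n_blocks")]
  jsonlite::write_json(writable, rp_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  report$artifacts$report <- rp_path
  say("wrote %d artifacts to %s", length(report$artifacts), output_dir)
  structure(report, class = "splint_run_report")
}

#' @export
print.splint_run_report <- function(x, ...) {
  cat("<splint_run_report>\n  stages:\n")
  for (nm in names(x$stages))
    cat(sprintf("    %-10s %6.2f s\n", nm, x$stages[[nm]]$seconds))
  if (!is.null(x$optimizer))
    cat(sprintf("  optimizer: %d iterations, converged %s\n",
                x$optimizer$iterations, x$optimizer$converged))
  cat(sprintf("  artifacts: %s\n",
              paste(basename(unlist(x$artifacts)), collapse = ", ")))
  invisible(x)
}

#' Resume the pipeline from an intermediate artifact
#'
#' Mirrors the OBJ/STL hand-off between the drafting, optimizing and solid
#' stages: `"optimize"` resumes from a draft shell OBJ, `"solidify"` from
#' an optimized shell OBJ, `"split"` from a whole solid STL.
#'
#' @param config a [pipeline_config()].
#' @param stage one of `"optimize"`, `"solidify"`, `"split"`.
#' @param artifact path to the preceding stage's output.
#' @param output_dir output directory.
#' @param quiet suppress progress messages.
#' @return a `splint_run_report` for the executed tail of the pipeline.
#' @export
stage_resume <- function(config, stage = c("optimize", "solidify", "split"),
                         artifact, output_dir, quiet = FALSE) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- suppressMessages(read_mesh(artifact))
  val <- validate_mesh(mesh, expect_closed = (stage == "split"),
                       check_intersections = FALSE)
  report <- list(config = unclass(config), config_hash = config_hash(config),
                 stages = list(), artifacts = list(), validation = list())

  if (stage %in% c("optimize", "solidify")) {
    if (val$watertight)
      stop("resume error: stage '", stage, "' expects an open shell, got a ",
           "closed mesh")
    if (val$n_nonmanifold_edges > 0L)
      stop("resume error: artifact is non-manifold")
  } else {
    if (!val$watertight)
      stop("resume error: stage 'split' expects a closed solid")
  }

  opt_shell <- NULL
  solid <- NULL
  if (stage == "optimize") {
    opt_params <- do.call(optimizer_params, config$optimizer)
    lattice <- extract_lattice(mesh)
    opt <- optimize_lattice(lattice, mesh, opt_params)
    opt_shell <- surface_mesh(opt$nodes, mesh$faces)
    opt_path <- file.path(output_dir, "optimized_shell.obj")
    write_mesh(opt_shell, opt_path)
    report$artifacts$optimized_shell <- opt_path
    report$optimizer <- list(iterations = attr(opt, "iterations"),
                             converged = attr(opt, "converged"))
  } else if (stage == "solidify") {
    opt <- extract_lattice(mesh)
    opt_shell <- mesh
  }

  if (stage %in% c("optimize", "solidify")) {
    sp <- strut_params(config$strut$diameter_mm,
                       method = config$strut$union_method,
                       voxel_pitch = if (is.null(config$strut$voxel_pitch_mm))
                         config$strut$diameter_mm / 8
                       else config$strut$voxel_pitch_mm)
    if (stage == "solidify") opt <- extract_lattice(mesh)
    solid <- strut_solid(if (stage == "optimize")
      extract_lattice(opt_shell) else opt, sp)
    blocks <- plan_blocks(opt_shell, config$blocks)
    solid <- attach_blocks(solid, blocks)
    solid_path <- file.path(output_dir, "splint_solid.stl")
    write_mesh(solid, solid_path)
    report$artifacts$solid <- solid_path
    report$blocks <- blocks
  } else {
    solid <- mesh
    class(solid) <- c("solid_model", "splint_mesh")
  }

  pieces <- split_solid(solid, as_cut_plane(config$split_plane))
  top_path <- file.path(output_dir, "piece_top.stl")
  bottom_path <- file.path(output_dir, "piece_bottom.stl")
  write_mesh(pieces$first, top_path)
  write_mesh(pieces$second, bottom_path)
  report$artifacts$piece_top <- top_path
  report$artifacts$piece_bottom <- bottom_path
  report$solid <- solid
  report$pieces <- pieces
  structure(report, class = "splint_run_report")
}
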