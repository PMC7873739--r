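# shared fixtures, built once per session and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# binary sphere volume: radius r, spacing sp, padded box
sphere_volume <- function(r = 8, sp = 0.6, hu_in = 1000, hu_out = 0) {
  half <- r + 3
  axv <- seq(-half, half, by = sp)
  d <- length(axv)
  g <- expand.grid(axv, axv, axv)
  vox <- array(ifelse(rowSums(g^2) <= r^2, hu_in, hu_out), c(d, d, d))
  ct_volume(vox, sp, origin = rep(-half, 3))
}

sphere_surface <- function(r = 8, sp = 0.6) {
  cached(sprintf("sphere_%g_%g", r, sp),
         extract_surface(segment(sphere_volume(r, sp), 500)))
}

default_phantom <- function() {
  cached("phantom_default", generate_phantom(phantom_spec()))
}

noiseless_phantom <- function() {
  cached("phantom_noiseless", generate_phantom(phantom_spec(noise_sd = 0)))
}

edge_lengths <- function(mesh) {
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2))
}

# straight-sided bar mesh with materials, cached with its stiffness matrix
bar_model <- function() {
  cached("bar_model", {
    mesh <- tetrahedralize(assembly(bone = make_box(c(0, 0, 0), c(40, 4, 4))), 1)
    mesh$E[] <- 1000
    mesh$nu[] <- 0.3
    list(mesh = mesh, K = sacronav:::assemble_stiffness(mesh))
  })
}

# screw-in-block toy FE model with assigned materials and node sets
toy_screw_model <- function() {
  cached("toy_screw_model", {
    plan <- trajectory_plan("S1", c(10, 10, 20), c(0, 0, -1),
                            screw_spec(length = 16, diameter = 5,
                                       head_diameter = 8, head_height = 4,
                                       head_offset = 3))
    assy <- place_screw(assembly(bone = make_box(c(0, 0, 0), c(20, 20, 20))),
                        plan)
    vol <- ct_volume(array(300, c(36, 36, 36)), 1, origin = c(-4, -4, -4))
    mesh <- assign_element_materials(tetrahedralize(assy, 2), vol,
                                     density_modulus_model())
    sets <- define_node_sets(mesh, list(depth = 2), 1 / 3,
                             head_spec = list(plan = plan))
    list(mesh = mesh, sets = sets, plan = plan, volume = vol)
  })
}

# nine-size convergence sweep on a lattice-aligned toy: a square-prism
# "screw" whose faces sit on multiples of 10 mm, so the bone-implant
# interface is represented identically at the finest sizes and the sweep
# isolates pure h-refinement
toy_sweep <- function() {
  cached("toy_sweep", {
    assy <- assembly(bone = make_box(c(0, 0, 0), c(30, 30, 30)))
    assy$screws[["S1"]] <- make_box(c(10, 10, 10), c(20, 20, 57))
    plan <- trajectory_plan("S1", c(15, 15, 30), c(0, 0, -1),
                            screw_spec(length = 20, diameter = 10,
                                       head_diameter = 10, head_height = 18,
                                       head_offset = 9))
    vol <- ct_volume(array(300, c(45, 45, 70)), 1, origin = c(-6, -6, -6))
    convergence_sweep(assy, seq(2, 6, by = 0.5), vol,
                      density_modulus_model(), plan,
                      load_case(500, c(0, 0, 1)),
                      endplate_region = list(depth = 2, xlim = c(0, 8)),
                      caudal_fraction = 1 / 3)
  })
}
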