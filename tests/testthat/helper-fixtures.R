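# Shared fixtures: geometries are built in code; expensive objects (integral
# handles, converged SCF points) are memoized for the whole test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# symmetric water monomer (angstrom -> bohr); its minimal distance between
# fit-grid points and exclusion spheres is ~9e-4 bohr, safely above the 1e-4
# finite-difference step
water_xyz <- function() {
  ang2bohr(rbind(c(0, 0, 0.1173),
                 c(0, 0.7572, -0.4692),
                 c(0, -0.7572, -0.4692)))
}

water_qm <- function() qm_region(c("O", "H", "H"), water_xyz())

# three MM point charges around the water, one with an LJ site
mm_three_charges <- function() {
  mm_region(c("O", "H", "H"),
            rbind(c(5.5, 0.5, 0.2), c(-0.8, 5.2, 1.0), c(0.3, -5.8, -0.6)),
            charges = c(-0.8, 0.45, 0.35),
            sigma = c(ang2bohr(3.15), 0, 0),
            epsilon = c(0.1521 / units_au$kcalmol_per_hartree, 0, 0),
            molecule = c(1L, 2L, 3L))
}

qmmm_water_sto3g <- function() {
  memo("pt_sto3g", {
    sys <- qmmm_system(water_qm(), mm_three_charges(), basis = "sto-3g",
                       scf_conv = 1e-11)
    prepare_point(sys, n_states = 2)
  })
}

water_631gs_handle <- function() {
  memo("h_631gs", {
    h <- electronic_structure(water_qm(), "6-31g*")
    solve_scf(h)  # warm the ERI cache
    h
  })
}

water_631gs_scf <- function() memo("scf_631gs", solve_scf(water_631gs_handle()))

water_631gs_ops <- function() {
  memo("ops_631gs", {
    h <- water_631gs_handle()
    fit_charge_operators(build_grid(water_qm()), water_qm(), h)
  })
}

ang2bohr <- espfqmm:::ang2bohr
bohr2ang <- espfqmm:::bohr2ang

expect_max_abs <- function(x, tol) expect_lt(max(abs(x)), tol)
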