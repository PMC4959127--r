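## shared fixtures: the reference incisor parameter set, built in code
ref_geom <- function() root_geometry(h = 13.0e-3, b = 3.9e-3, e = 0.6,
                                     delta = 0.229e-3)
ref_material <- function() pdl_material(E_inf = 680e3, nu = 0.49)
ref_kernel <- function() fractional_kernel(gamma = 0.35, tau_sigma = 550,
                                           nu_sigma = 1.3e3)

## moderate-resolution stiffness, cached across tests within a session
ref_stiffness <- local({
  S <- NULL
  function() {
    if (is.null(S)) S <<- assemble_stiffness(ref_geom(), ref_material(),
                                             n_r = 128L, n_phi = 128L,
                                             check = FALSE)
    S
  }
})

## published coefficient set (N/m, N m, N)
published_coeffs <- c(a11 = 5.043e6, a22 = 1.090e6, a33 = 6.997e6,
                      a44 = 578.9, a55 = 6.137, a66 = 445.6,
                      a16 = -44.168e3, a34 = 59.060e3)

## crest meridian point of the reference geometry
crest_x <- function(geom = ref_geom()) geom$b / sqrt(1 - geom$e^2)
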