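# Phantom parameter builders shared across tests. The short (20-slice)
# variants keep unit tests fast; geometry in-plane is the full desk scale.

phShort <- function(seed = 1L, ...) {
  phantomParams(shape = c(276L, 276L, 20L),
                soma = list(theta_halfwidth = 0.55, z_range = c(5L, 16L),
                            extra_thickness = 160),
                nuclei = list(ec = list(theta = pi / 2, z = 10,
                                        semi_nm = c(40, 300, 250)),
                              pc = list(z = NA, semi_nm = c(90, 90, 250),
                                        lobe_offset_slices = 0L)),
                peg_specs = rbind(pegSpec("PC-EC", z = 10),
                                  pegSpec("EC-PC", z = 10)),
                elp_specs = NULL,
                seed = seed, ...)
}

# bare tube: EC + PC arc only, no junction/soma/nuclei/ER/ELPs; pegs as given
phBare <- function(seed = 1L, pc_coverage = 0.64, peg_specs = NULL,
                   nz = 20L, ...) {
  phantomParams(shape = c(276L, 276L, nz), pc_coverage = pc_coverage,
                soma = NULL, junction = NULL, er = NULL, elp_specs = NULL,
                nuclei = list(ec = NULL, pc = NULL), n_mito = c(0L, 0L),
                peg_specs = peg_specs, seed = seed, ...)
}
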