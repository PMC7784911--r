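# Shared fixtures, all generated in code.

# Single-tissue phantom spec: every voxel one tissue, no blood label.
single_tissue_spec <- function(grid = c(10, 10, 10), t1 = 1.0, m0 = 1000,
                               ktrans = 3e-3, vp = 0.02,
                               noise_model = "none", snr = NULL, seed = 1L) {
  tis <- data.frame(label = 1L, name = "tissue", t1 = t1, m0 = m0,
                    ktrans = ktrans, vp = vp)
  phantom_spec(grid_shape = grid, tissues = tis,
               label_map = array(1L, grid), vif_label = -1L,
               noise_model = noise_model, snr = snr, seed = seed)
}

# Exact input function recovered from a tiny noiseless all-blood phantom.
clean_vif <- function() {
  bl <- data.frame(label = 1L, name = "blood", t1 = 1.65, m0 = 1100,
                   ktrans = 0, vp = 1)
  sp <- phantom_spec(grid_shape = c(4, 4, 4), tissues = bl,
                     label_map = array(1L, c(4, 4, 4)), vif_label = 1L)
  ph <- generate_phantom(sp)
  t1m0 <- fit_vfa_t1(ph$vfa, ph$b1_map)
  conc <- signal_to_concentration(ph$dynamic, t1m0, ph$b1_map)
  extract_vif(conc, array(TRUE, c(4, 4, 4)))
}

# Group-by-region mean matrices with no group effect (null) or with a
# uniform PD shift expressed in between-subject SDs.
null_means_ktrans <- function(pd_shift_sd = 0, sd_b = 0.8e-3) {
  base <- c(SN = 3.0e-3, CA = 2.5e-3, PU = 2.5e-3, P = 2.0e-3,
            WML = 3.5e-3, NAWM = 1.8e-3, FC = 3.2e-3, PC = 3.0e-3)
  m <- rbind(CN = base, CP = base, PD = base + pd_shift_sd * sd_b)
  m
}

null_means_vp <- function() {
  base <- c(SN = 0.010, CA = 0.015, PU = 0.014, P = 0.010,
            WML = 0.007, NAWM = 0.006, FC = 0.020, PC = 0.018)
  rbind(CN = base, CP = base, PD = base)
}

# Smoothed standard-normal noise map, for voxelwise-statistics nulls.
smooth_noise_map <- function(dm = c(16, 16, 8), fwhm = 3,
                             voxel = c(1.5, 1.5, 4)) {
  gaussian_smooth(array(stats::rnorm(prod(dm)), dm), fwhm, voxel)
}
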