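# metascint

Simulator and reconstructor for scintillation X-ray imaging through an
optical convolution metasurface, for imaging scientists who want a
desk-scale, fully seeded model of the whole chain: optical encoding,
noisy capture, decoder calibration, deconvolution, and evaluation.

## The model in brief

A scintillator (Ce:YAG, n = 1.82) converts X-rays to visible light, but
total internal reflection traps the steep-angle emission: only the escape
cone `(1 - cos θc)/2` with `θc = asin(1/n)` leaves one face — an ~92 %
photon loss. A periodic metasurface of period ξ on the exit face diffracts
trapped light back into the optics according to the transmission grating
equation

    s = n sin θ − m λ/ξ ,   propagating iff |s| < 1,

admitted when the exit angle `asin s` falls within the system's acceptance
half-angle ε. All admitted (θ, λ, m) rays aggregate incoherently into a
point-spread function K (the optical convolution kernel), which also earns
a *collection gain* — how much more light it steers into the acceptance
cone than the plain interface. A detector frame is

    Ŝ = BIN( Poisson(t_cap · r · gain · (I ⊗ K)) + N(0, σ_read) ),

and the electronic decoder is learned from **one** calibration exposure of
a known sample by minimizing the least-squares inference target

    Ω(K) = ‖ Ŝ − I_known ⊗ K ‖²_F

(projected gradient with per-epoch nonnegativity projection and unit-sum
renormalization), then applied to any sample by Richardson–Lucy
deconvolution. Evaluation follows the field's conventions:
frequency-resolved SNR in dB normalized on an ultra-high-frequency noise
band, region-to-blank intensity ratios, contrast-to-noise ratios
`(1 − r_A)/(1 − r_B)`, 2D Fourier spectra, and a parallel-beam tomography
loop (Radon projection → per-projection degradation and decoding →
ramp-filtered back-projection).

## Worked example

```r
library(metascint)
cat(sprintf("photon loss: %.1f%%\n", 100 * (1 - escape_fraction(1.82))))

sys  <- optical_system()            # n = 1.82, eps = 10 deg, L = 50 um
spec <- emission_spectrum()         # uniform 400-700 nm
k_tex <- build_psf(metasurface(300, "grating_1d"), sys, spec)
cat(sprintf("texture kernel: %d x %d, collection gain %.2f\n",
            nrow(k_tex$grid), ncol(k_tex$grid), k_tex$collection_gain))

# one calibration exposure of a known glyph sample trains the decoder
calib <- make_glyph_phantom(c(256, 256), "239")
calib_shot <- capture(calib, k_tex, exposure_settings(t_cap_ms = 100, seed = 1))
est <- estimate_kernel(calibration_pair(calib, calib_shot))
cat(sprintf("decoder trained: %d epochs, final loss %.2f (%s)\n",
            est$trace$epochs, est$final_loss, est$status))

# decode a 3 um fringe card captured through the same optics
fringe <- make_fringe_phantom(c(256, 256), pitch_um = 3, n_lines = 7,
                              pixel_pitch_um = 0.5)
k_fr <- build_psf(metasurface(300, "grating_1d"), sys, spec,
                  grid_shape = c(41, 41), pixel_pitch_um = 0.5)
shot <- capture(fringe, k_fr, exposure_settings(bin_factor = 1, noiseless = TRUE))
rec  <- richardson_lucy(shot, k_fr, iterations = 30)
prof_shot <- section_profile(shot$counts, c(128, 10), c(128, 247), width = 5)
prof_rec  <- section_profile(rec$image,  c(128, 10), c(128, 247), width = 5)
cat(sprintf("fringe minima: %d in the raw shot, %d after decoding (truth: 7)\n",
            count_profile_minima(prof_shot), count_profile_minima(prof_rec)))
```

prints

```
photon loss: 91.8%
texture kernel: 33 x 33, collection gain 3.69
decoder trained: 60 epochs, final loss 8.33 (converged)
fringe minima: 2 in the raw shot, 7 after decoding (truth: 7)
```

The loss line says the 300 nm grating rescues photons that the plain
interface would lose (3.69× collection), and the last line is the point of
the whole construction: the raw encoded frame shows only 2 of the 7
absorption lines, while the learned decoder restores all 7.

Higher-level experiments are bundled as scenarios:

```r
rep <- run_scenario(scenario_config("regional_vs_texture", seed = 1))
aggregate(cbind(snr_high_db, snr_low_db, cnr) ~ arm, rep$summary, mean)
```

which captures a two-region scene (smooth tube next to a textured fin)
through three arms — plain system, 300 nm texture kernel, 500 nm isotropic
regional kernel — trains a decoder per arm on a glyph calibration, and
tabulates band-resolved SNR and the tube/fin CNR over five replicate
seeds.

There is also a thin command-line front end at `inst/cli/metascint.R`
(subcommands `psf`, `simulate`, `train`, `reconstruct`, `metrics`, `tomo`,
`run`).

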