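# nchr — noise-compensated homotopic non-local reconstruction for rapid SD-OCT

Spectral-domain optical coherence tomography (SD-OCT) acquires complex
k-space coefficients `F(k)`; the B-scan is their inverse Fourier transform
`f(x) = F⁻¹F(k)`. Pushing the A-scan rate up (e.g. from a 47 kHz camera
baseline to 4x or 8x that) shortens the detector exposure, inflates the
measurement noise roughly in proportion to speed, and drags the tomogram
SNR down with it. `nchr` reconstructs such rapid acquisitions instead of
just inverse-transforming them, for researchers who want high-rate retinal
imaging without the SNR penalty — and for anyone who wants a fully
synthetic, self-contained testbed for this class of algorithms.

The core is a homotopic continuation on the regularization bandwidth σ:

    f̂(x) = lim_{σ→0} argmin_f ρ(f, σ)   s.t.   |F̂(k) − F(k)| ≤ δ  ∀k

with the non-local patch penalty and modified James-Stein weights

    ρ(f, σ)   = Σ_x Σ_{i∈N(x)} w(x,i,σ) ‖R(x) − R(i)‖²
    w(x,i,σ)  = α(x,i) · (1 − (m−2)σ² / ‖f(x) − f̂(x)‖²)₊ · exp(−‖R̂(x) − R̂(i)‖² / 2σ²)

Each outer iteration runs frozen-weight steepest descent on ρ in the
spatial domain, then projects the spectrum of the estimate back into the
δ-ball around the raw measurements (noise compensation, with δ = κ × the
system noise floor). SNR/CNR quality metrics, a layered speckled-phantom
simulator with speed-scaled detector noise, and a CLI round out the
toolkit. The patch geometry (9×9 patches, 21×21 neighborhoods) and the
operating point σ₁ = 0.3, λ = 0.7 are the method's published settings on
intensity-normalized B-scans.

## Worked example

```r
library(nchr)

# a 128x128 layered retina-like phantom, speckled, acquired at 4x speed
scene <- generate_phantom(default_phantom_spec(seed = 1))
acq   <- acquisition_model(speed_factor = 4, base_noise_std = 0.03, seed = 1)
meas  <- simulate_acquisition(scene, acq)
meas$delta <- estimate_delta(meas, noise_std = meas$meta$noise_std, kappa = 3)

naive <- naive_reconstruction(meas)     # plain inverse transform
cnr(naive, scene$rois)
#> SNR: 35.865 dB   CNR: 1.6991 (5 regions)

rec <- reconstruct(meas, recon_config())
rec
#> nchr reconstruction: 128x128 image, 2 outer iterations (converged), delta = 0.18
cnr(rec$image, scene$rois)
#> SNR: 55.637 dB   CNR: 1.9084 (5 regions)
```

The naive reconstruction of this 188 kHz-equivalent acquisition sits at
35.9 dB; the reconstruction lifts it to 55.6 dB (+19.8 dB) and raises the
contrast-to-noise ratio of the five layer ROIs from 1.70 to 1.91, while
every reconstructed k-space coefficient stays within δ = 0.18 of its
measured value (`max(rec$trace$max_kdev)` = 0.153).

The same pipeline is scriptable from a shell (see `inst/scripts/nchr`):

```sh
nchr simulate   --out kspace.json --speed-factor 4 --seed 1
nchr reconstruct --input kspace.json --output recon.tif --trace trace.jsonl
nchr metrics    --image recon.tif --background-mask bg.png --roi-mask r1.png,r2.png
```

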