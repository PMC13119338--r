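# fretburst

Burst-level single-molecule FRET analysis with pulsed interleaved
excitation (PIE/ALEX), and two-state kinetic inference for time-resolved
measurements on freely diffusing molecules — built for experiments such
as poly(ADP-ribose)-induced nucleosome decompaction followed in a
droplet-based microfluidic mixer, where reaction times from milliseconds
to ~60 s map onto positions along an observation channel.

## Who it is for, and what it computes

Single-molecule spectroscopists who record photon streams from diffusing
FRET-labeled molecules and need population fractions and rates. The
package covers the full chain:

* **Burst search** by fixed-bin thresholding (40 photons / 500 µs bin in
  droplet mode; 60 photons / 1 ms in manual-mixing mode), merging
  consecutive hot bins, with per-photon PIE excitation-window
  classification.
* **Corrections** for background, donor leakage (α), acceptor direct
  excitation (δ) and the γ factor, giving per-burst transfer efficiency
  and stoichiometry

  $$E = \frac{F_{DA}}{\gamma F_{DD} + F_{DA}},\qquad
    S = \frac{\gamma F_{DD} + F_{DA}}{\gamma F_{DD} + F_{DA} + F_{AA}},$$

  with stoichiometry gating (e.g. 0.2 < S < 0.8) to remove donor-only
  and acceptor-only molecules.
* **Global histogram fitting**: transfer-efficiency histograms of all
  time points fitted together with two Gaussian peaks — shared
  positions, widths constrained to photon-counting (shot-noise) values,
  free non-negative amplitudes; population fractions from fractional
  peak areas.
* **Two-state pseudo-first-order kinetics**:
  $f(t) = f_\infty - (f_\infty - f_0)e^{-k_{\mathrm{obs}}t}$, fitted by
  weighted least squares; position→time mapping for droplet mixers
  (default velocity 0.6 mm/s) and one-minute segmentation of slow
  manual-mixing traces.
* **Synthetic photon streams** with known ground truth (two-species
  mixtures evolving by the two-state law, donor-only contaminants,
  background, crosstalk, direct excitation, γ distortion, 20 MHz PIE
  timing), for validating every stage without instrument data.
* **Trajectory companions** for coarse-grained simulations: Förster
  efficiencies ($R_0 = 5.4$ nm), contact counts/lifetimes (1.2 nm
  cutoff), and WHAM potentials of mean force from umbrella windows.

## Worked example

Simulate a droplet-mixer kinetic series at the reference condition
(compact nucleosomes at E = 0.36 opening to the decompacted state at
E = 0.053 with k = 0.42 s⁻¹), then run the complete analysis:

```r
library(fretburst)

instr <- instrument_spec()                       # 20 MHz PIE, ~25 ns delay
mix   <- mixture_time_course(k_obs = 0.42, f0 = 0.2, f_inf = 0.9)
sim   <- simulate_kinetic_series(mix, instr, bursts_per_timepoint = 3000,
                                 seed = 1)
ana   <- analyze_droplet_series(sim$streams, sim$times, instrument = instr)
ana
#> droplet-mode analysis: 8 time points, 18969 gated bursts
#> global histogram fit: 2 peak(s) over 8 histogram(s)
#>   positions: 0.0510 0.3591  shot-noise widths: 0.0567 0.0744  (N_ref = 53.1)
#>   fraction compact (high-E peak area):
#>  timepoint fraction_compact      se
#>     0.0100            0.809 0.01041
#>     0.0296            0.783 0.01086
#>     0.0877            0.777 0.01106
#>     0.2599            0.733 0.01169
#>     0.7697            0.602 0.01280
#>     2.2797            0.364 0.01277
#>     6.7523            0.140 0.00904
#>    20.0000            0.100 0.00784
#> two-state fit: k_obs = 0.4296 +/- 0.012 /s, f0 = 0.197, f_inf = 0.9
#>   95% CI on k_obs: [0.3977, 0.4615]
```

Reading this output: the global fit finds the two shared peak positions
(decompacted 0.051, compact 0.359 — generator truths 0.053 and 0.36);
the compact fraction decays from ~0.80 toward 0.10 along the observation
channel; and the two-state fit recovers the decompaction rate
0.43 ± 0.01 s⁻¹ against a generator truth of 0.42 s⁻¹, with the initial
and equilibrium decompacted fractions (0.20, 0.90) returned as `f0` and
`f_inf`.

Slow manual-mixing traces follow the same pattern with
`simulate_slow_trace()` and `analyze_slow_trace()` (one-minute windows,
5-s mixing dead time). A thin command-line wrapper lives at
`inst/cli/fretburst` (subcommands `simulate`, `bursts`, `fret`,
`fit-hist`, `fit-kinetics`, `wham`, `run-all`; see `?cli_main`).

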