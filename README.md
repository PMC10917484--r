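# hessdenoise

Split-Bregman Hessian denoising for 3D fluorescence image stacks, in R.

Superresolution fluorescence stacks (e.g. structured-illumination
reconstructions) are noisy, while the structures they contain — filaments,
membranes, organelle tracks — are smooth and continuous in all three
dimensions. This package removes that noise by penalizing the L1 norm of the
six second-order spatial derivatives of the image (the 3D Hessian components
xx, xy, xz, yy, yz, zz):

    min_u  (mu/2) ||u - f||_2^2  +  sum_d w_d ||D_d u||_1

solved with the split-Bregman iteration: six independent per-direction
shrinkage/Bregman tasks followed by an FFT-based image update whose
denominator — the Fourier spectrum of the composite difference operator —
depends only on the stack shape and is persisted across runs.

The package is as much about *how* that computation is executed as about the
result. It maintains two paths and proves they agree:

* `denoise_reference()` — plain structure: function-call finite differences
  with temporary copies, no reuse, serial, binary64, fully instrumented
  (24 difference calls and 6 shrinkage executions per iteration).
* `denoise_optimized()` — vectorized preallocated differences, inlined
  operator bodies, de-duplicated first differences, persisted operator
  spectrum, uniform binary32 precision (overridable), six-task parallel
  backend, and a device-dispatch contract with single upload/gather.

At binary64 on CPU the two paths are **bit-identical**; at binary32 they
differ byte-wise (every 4-byte word at most one low-order byte, which
`byte_compare()` exposes) while agreeing to a max relative error below 1e-4.
Supporting tooling: a seeded filament-phantom generator, SNR/PSNR/RMSE/MAE
quality reports, line profiles, exact IEEE-754 decimal expansions
(`float_repr("0.3", "binary32")` → `0.300000011920928955078125`), and a
benchmark harness over the individual optimization stages.

For whom: microscopy image-analysis people who need a fast, *verifiable*
Hessian denoiser, and anyone using the two-path design as a worked example of
optimizing numerical code without changing its output.

## Worked example

```r
library(hessdenoise)

# synthetic ground truth: blurred filaments, background 0.05, Gaussian noise SD 0.1
ph <- make_phantom(phantom_spec(shape = c(64, 64, 32), gaussian_noise_sd = 0.1, seed = 42))

params <- denoise_params(mu = 2, iterations = 20, precision = "binary64")
res <- denoise_optimized(ph$noisy, params)
res
#> <denoise_result> 64 x 64 x 32 (binary64, cpu_serial), 20 iterations
#> <call_counters> forward: 0, backward: 0, shrink: 120, iterations: 20

quality(ph$clean, ph$noisy)      # how bad was the input
#> <quality_report> per-frame metrics, then mean +/- SD over frames
#>   snr   -0.447834 +/- 1.28
#>   psnr  17.3025 +/- 1.1
#>   rmse  0.100201 +/- 0.00102
#>   mae   0.0800405 +/- 0.000921
quality(ph$clean, res$stack)     # how good is the output
#> <quality_report> per-frame metrics, then mean +/- SD over frames
#>   snr   6.41371 +/- 0.464
#>   psnr  24.164 +/- 1.27
#>   rmse  0.0462118 +/- 0.00837
#>   mae   0.0181934 +/- 0.0032
```

Reading the numbers: the noisy input sits at the injected noise level
(per-frame RMSE ≈ 0.10 against ground truth; SNR is negative because most of
this mostly-dark stack is background). Twenty iterations at `mu = 2` cut the
RMSE against ground truth by half and raise the per-frame SNR by about 7 dB
while its counters show zero difference-operator calls — the optimized path
inlines them. The counters of the same run under `denoise_reference()` read
forward: 240, backward: 240, shrink: 120.

The instrumentation side:

```r
ref <- denoise_reference(ph$noisy, denoise_params(mu = 2, iterations = 100))
as.list(ref$counters)
#> $forward_calls       [1] 1200
#> $backward_calls      [1] 1200
#> $shrink_executions   [1] 600
#> $iterations_completed [1] 100
```

A command-line front end (subcommands `phantom`, `denoise`, `bench`,
`compare`, `float-repr`) is installed at `inst/cli/hessdenoise`:

```sh
Rscript inst/cli/hessdenoise phantom --out-noisy noisy.tif --shape 64,64,32 --seed 42
Rscript inst/cli/hessdenoise denoise --input noisy.tif --output den.tif --mu 2 --iters 20
Rscript inst/cli/hessdenoise bench --input noisy.tif --stages reference,dedup,single_precision --iters 20
```

Stacks travel as multi-page grayscale float32 TIFF (readable in Fiji);
binary64 payloads use the package's documented `.rawstack` container.

See `vignettes/hessian-denoising.Rmd` for the model, the zero-fill and
adjoint conventions, the precision policy, and the design decisions.

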