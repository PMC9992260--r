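Package: dircn
Title: Densely Interconnected Residual Cascading Networks for Accelerated MRI Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Unrolled cascaded reconstruction of undersampled multi-coil MRI.
    Implements centered orthonormal k-space operators, SENSE-style coil
    reduction and expansion with normalized sensitivity maps, equidistant
    Cartesian undersampling masks with a fully sampled center, soft k-space
    data consistency with a learnable weight, squeeze-and-excitation residual
    U-Net sub-networks with input-level dense connections and long-range
    interconnections between cascades, Gaussian-weighted SSIM / NMSE / PSNR
    evaluation, an SSIM plus L1 training objective, and a seeded multi-coil
    phantom simulator so the whole pipeline trains and evaluates on the CPU.
    Networks are trained with a built-in reverse-mode automatic
    differentiation engine and an AMSGrad Adam optimizer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr
Config/testthat/edition: 3
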