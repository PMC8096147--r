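Package: deazaRNA
Title: Thermodynamics, Exchange Kinetics and Hydration of Deazapurine-Modified RNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Biophysical analysis toolkit for RNA carrying 3- and 7-deazapurine
    nucleobases (c3A, c3G, c7A, c7G). Implements two-state analysis of UV
    melting profiles with molecularity-aware mass-action models (derivative
    melting temperatures, baseline-corrected folded fractions, van't Hoff
    fits, Tm-versus-concentration regression, Gibbs energies at 298.15 K and
    replicate aggregation), fitting of imino-proton/water exchange rates from
    CLEANEX-PM build-up curves with Monte-Carlo uncertainty and
    saturation-recovery water T1 support, nucleobase pKa determination from
    pH-dependent chemical shifts together with Watson-Crick donor-acceptor
    pKa-gap bookkeeping, and crystal-structure superposition with
    minor-groove hydration reports. A synthetic-data module generates every
    raw-data type the analyses consume, so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    bio3d,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
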