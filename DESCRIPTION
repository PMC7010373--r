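Package: ncfcheck
Title: Verified Enclosures for Noncentral Beta and F Power Calculations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Self-validating computation of the noncentral beta and
    noncentral F cumulative distribution functions, central beta upper
    quantiles, and the noncentrality parameter attaining a prescribed type II
    error, using outwardly rounded interval arithmetic, forward-mode interval
    automatic differentiation, and the univariate interval Newton method.
    Every reported interval is a mathematically guaranteed enclosure of the
    exact real-arithmetic result, which makes the package suitable for
    cross-checking power and minimal-detectable-difference computations of
    other statistical software. Includes a batch cross-checking tool that
    reads candidate values from plain text files and issues verified,
    rejected or failed verdicts per record.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
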