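# asphkit

Analysis toolkit for substrates of **aspartate/asparagine-β-hydroxylase
(AspH)**, the 2-oxoglutarate- and Fe(II)-dependent oxygenase that
β-hydroxylates Asp/Asn residues of EGF-like domains (EGFDs). The package
is aimed at proteomics and enzymology groups who want to (i) scan
protein sequences for candidate AspH sites, (ii) confirm and localize
hydroxylation from tandem-MS fragment data, and (iii) quantify substrate
turnover with Michaelis–Menten kinetics — each stage testable against
seeded synthetic data with known ground truth.

## The science in brief

**Consensus scanning.** The classical AspH substrate consensus is the
12-residue pattern

```
C3 - X - D/N - X - X - X - X - F/Y - X - C4 - X - C5
```

with the acceptor D/N at position 3 and the TPR-binding aromatic F/Y at
position 8. Biochemical evidence shows the true requirement is only the
disulfide-bridged **10-residue macrocycle** closed by the two cysteines
(C3–C4 in EGFD numbering) — the trailing C4-X-C5 is dispensable.
`scan_legacy()` and `scan_revised()` implement both rules; every legacy
hit is provably a revised hit, and sites are flagged `both` or
`revised_only` (the fibulin-type case). `index_cysteines()` and
`c4_c5_spacing()` support the C1…Cn ordinal bookkeeping used to
describe EGFD disulfide patterns.

**MS/MS evidence.** Hydroxylation adds one oxygen,
Δm = +15.994915 Da. In a b/y fragment series the shift appears in
exactly the fragments that span the modified residue, so comparing
matched shifted/unshifted ions brackets the site:
`theoretical_by_ions()`, `match_peaks()`, `localize_site()`. Site
occupancy is estimated label-free as `100·Ih/(Ih+Ib)` from the
hydroxylated and base peptide intensities (`estimate_occupancy()`),
defined only when the base peptide was detected.

**Kinetics.** SPE-MS turnover assays report
`% conversion = 100·(product integral)/(substrate + product integral)`.
The package simulates noiseless progress curves from the integrated
Michaelis–Menten relation `Km·ln(S0/S) + (S0 − S) = kcat·E_active·t`,
extracts initial rates, fits `v = vmax·S/(Km+S)` by nonlinear least
squares, and converts vmax to kcat with the active-site-titration
correction `kcat = vmax/(E_total · active fraction)` (default prep:
0.1 µM enzyme, 95.1 ± 14.3 % active); `kcat/Km` is reported in
mM⁻¹·s⁻¹.

## Worked example

```r
library(asphkit)

## 1. a seeded proteome with planted motif instances, then scan it
ds <- generate_proteome(seed = 42, n_proteins = 10,
                        length_range = c(150, 250),
                        n_legacy = 2, n_revised_only = 2, n_near_miss = 2)
scan_proteome(ds$records)
#>   accession    rule ring_start ring_end site_position site_residue
#> 1   SYN0002 revised        148      157           150            N
#> 2   SYN0003 revised         62       71            64            N
#> 3   SYN0004 revised        103      112           105            D
#> 4   SYN0004 revised        156      165           158            D
#>   aromatic_residue domain_label         flag c4_c5_spacing
#> 1                Y         <NA> revised_only            NA
#> 2                F         <NA> revised_only            NA
#> 3                Y         <NA>         both            NA
#> 4                F         <NA>         both            NA
```

The four reported sites are exactly the four planted true motifs
(`ds$truth`): the two legacy plants are flagged `both`, the two
macrocycles without a C5 are `revised_only`, and the two near-misses
(acceptor E, aromatic W) are correctly rejected.

```r
## 2. fit kinetics from rate data and derive turnover numbers
s <- c(1, 2, 5, 10, 20, 50)                       # uM substrate
pts <- data.frame(substrate = s, rate = 0.029 * s / (7.9 + s))
fit <- fit_michaelis_menten(pts)
rep <- mm_fit_report(fit, enzyme_prep(0.1, 0.951, 0.143))
rep$reported
#> $kcat       0.3        # s^-1, = 0.029 / (0.1 * 0.951), 2 dp
#> $km         7.9        # uM, 2 sf
#> $efficiency 38         # mM^-1 s^-1, from the rounded kcat

## 3. simulate the corresponding progress curve at assay composition
simulate_progress(kcat = 0.30, km = 7.9, prep = enzyme_prep(0.1, 0.951),
                  substrate_initial = 2.0, times = c(0, 60, 120, 300, 600))
#>   time_s substrate_uM product_uM conversion_pct
#> 1      0    2.0000000  0.0000000        0.00000
#> 2     60    1.6774749  0.3225251       16.12626
#> 3    120    1.3991169  0.6008831       30.04416
#> 4    300    0.7890069  1.2109931       60.54966
#> 5    600    0.2846334  1.7153666       85.76833
```

So a substrate with kcat 0.30 s⁻¹ and Km 7.9 µM reaches ~86 % conversion
in 10 min under the standard assay composition, consistent with the
">80 % in 10 min" behavior of an efficient cyclic-peptide substrate.

A shell entry point with subcommands `scan`, `localize`, `occupancy`,
`kinetics`, `simulate` is provided at `inst/cli/asph.R`
(`Rscript inst/cli/asph.R scan proteome.fasta --out results/`).

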