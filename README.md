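# difmod

Detection and analysis of Xer/dif recombination sites and *dif* modules in
bacterial replicons.

## The problem

The XerC/XerD site-specific recombination system resolves chromosome dimers
at a single 28-bp *dif* site near the replication terminus. In
*Acinetobacter*, plasmids often carry many *dif*-like sites (p*dif* sites),
and pairs of sites can flank adaptive cargo genes (tellurium, chromium and
organic-peroxide resistance, sulfate and potassium transporters,
toxin–antitoxin pairs), forming **dif modules** — simple Xer-dependent
mobile genetic elements. `difmod` is for microbial genomicists who want to
screen plasmid, chromosome or contig sequences for these elements and
reason about their mobility, reproducibly and with tested code.

## The method in brief

A *dif* site is a fixed 28-bp element `[11-bp XerC arm | 6-bp central |
11-bp XerD arm]`, occurring on the forward strand in CD (XerC/XerD) or DC
(XerD/XerC) arm order. For a window *w* and reference *r*,

    identity(w, r) = #{ i : w_i = r_i , w_i, r_i ≠ N } / 28

and a site call requires `identity ≥ t` (default *t* = 0.75, i.e. ≥ 21
matches) against any of {CD, DC, rc(DC), rc(CD)} — the four comparisons make
the scan exactly strand-symmetric. A **module** is the inclusive span
between consecutive sites (both 28-bp sites counted) carrying a cargo ORF; a
module family shows **mobility evidence** when two copies with global
identity ≥ 0.98 sit on different replicons in flanking contexts that align
below 0.80 identity. Sites are clustered by single-linkage at 0.95 (at 28 bp:
one mismatch links, two do not), and site groups are profiled by
per-position information content `2 − H` (bits) and compared by per-position
Jensen–Shannon divergence.

The packaged 28-bp reference pair and cargo catalog are clearly-labelled
synthetic stand-ins (consensus-style site architecture; random ORFs with the
published cargo-gene lengths); both are drop-in replaceable via
`reference_sites(path)` and `read_cargo_catalog(path)` for real-data work.
See `vignettes/difmod-methods.Rmd` for the full model, parameter rationale
and limitations.

## Worked example

Generate a small synthetic plasmid collection with planted ground truth,
scan it, call and label modules, assess mobility, and profile the sites:

```r
library(difmod)

ds    <- generate_dataset(simulation_spec(n_replicons = 12, seed = 42))
sites <- scan_replicons(ds$replicons)
head(sites[, c("replicon_id", "start", "end", "orientation", "identity")], 4)
#>   replicon_id start  end orientation  identity
#> 1  synth_p001  2101 2128          DC 0.9642857
#> 2  synth_p001  2464 2491          CD 0.9285714
#> 3  synth_p001  2882 2909          CD 0.7500000
#> 4  synth_p001  3180 3207          CD 0.9642857

mods <- do.call(rbind, lapply(ds$replicons, function(r)
  call_modules(sites[sites$replicon_id == r$id, , drop = FALSE], r)))
mods <- label_modules(mods, read_cargo_catalog())
mods[mods$label != "unlabeled", c("replicon_id", "start", "end", "length", "label")]
#>              replicon_id  start    end length           label
#> synth_p004.2  synth_p004 125123 126343   1221        terC_dif
#> synth_p009.1  synth_p009  17355  20365   3011   chrA-chrB_dif
#> synth_p009.3  synth_p009  22489  25037   2549  kup-orf210_dif
#> synth_p010.1  synth_p010   1329   3487   2159 sulP-orf198_dif
#> synth_p010.3  synth_p010   9387  11935   2549  kup-orf210_dif
#> synth_p011.1  synth_p011 169325 170545   1221        terC_dif
#> synth_p011.2  synth_p011 193971 195033   1063    ohr-ohrR_dif
#> synth_p012.1  synth_p012  16736  19746   3011   chrA-chrB_dif

occ   <- module_occurrences(mods, ds$replicons)
calls <- assess_all_families(occ)
#> mobile family: terC_dif with 2 occurrences
#> mobile family: chrA-chrB_dif with 2 occurrences
#> mobile family: kup-orf210_dif with 2 occurrences

prof <- build_profile(sites, "detected pdif sites")
prof
#> <position_profile> detected pdif sites: 44 sites
#>  consensus: ATTTCGTATAAGGTGTATTATGTCAATT
#>  mean info: 1.71 bits
round(conservation_ranking(prof)$region_info, 3)
#> xerC_arm  central xerD_arm
#>    1.711    1.625    1.759
```

Reading of the numbers: the scanner recovers the planted sites with their
exact coordinates and realised identities (0.75–1.0 here, i.e. 21–28 of 28
positions matching); the labelled module lengths are exactly the planted
template spans (e.g. the terC module is 1221 bp inclusive of both flanking
sites); the three planted transfer events — and nothing else — come back as
mobile families; and the detected sites show the conservation ordering
expected of genuine *dif* sites (XerD arm most conserved, central region
least).

A thin command-line front end over the same functions ships in
`inst/cli/difmod` (`difmod scan|modules|mobility|cluster|logo|summarize|simulate`).

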