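# petdecon

Blind deconvolution of protein occupancy and interaction calling from
ChIA-PET read pairs.

ChIA-PET libraries mix two kinds of ligation products. *Self-ligation*
pairs come from a single protein-bound fragment and carry the −+
orientation with a short span, so they sample the marginal occupancy of
the profiled protein convolved with the sonication-induced *read spread
function* (RSF). *Inter-ligation* pairs join two different bound
fragments and sample the joint occupancy of pairs of genomic locations.
petdecon exploits both:

1. **Self/inter classification** — a distance mixture over −+ pairs.
   The inter fraction among −+ pairs is estimated from the other three
   orientation classes (which can only arise by inter-ligation), and
   each −+ pair gets a posterior self-ligation weight from weighted
   kernel density estimates of the two span distributions, with
   bandwidths chosen by least-squares cross-validation.
2. **Blind deconvolution** — the 2D density of self-ligation end pairs
   in a training window is factored into a 1D occupancy profile and a
   2D RSF by alternating Richardson–Lucy updates on a band matrix.
   The RSF peak offset ⟨−λ, λ⟩ estimates half the modal sonication
   fragment length; the occupancy is then extended genome-wide through
   a diagonal-slice shortcut that only needs a 1D midpoint density.
3. **Conditional joint occupancy** — inter-ligation pairs are spread
   through the RSF and weighted by marginal occupancy to give, at each
   anchor (e.g. a transcription start site), a profile of jointly
   occupied distal locations.
4. **Significance with undersampling correction** — candidate distal
   regions are tested with an exact P(Y > Z) binomial comparison of
   joint mass against marginal occupancy, after a missing-mass fixed
   point (τ) inflates each anchor's observed total toward its
   full-sampling share; the inflation scale c is calibrated so that
   single-pair calls make up at most a small target fraction of the
   significant set.

Everything is tibble-first: fits have `tidy()`/`glance()` methods,
tracks and calls are plain tibbles, and diagnostic `autoplot()` methods
return ggplot objects.

## Worked example

The package ships a self-contained simulator whose default scenario has
two 2 Mb chromosomes, 20 anchor sites, 20 distal sites, 20 planted
anchor–distal loops spanning 5–500 kb, 30,000 self-ligation pairs,
3,000 loop pairs and 3,000 uniform-noise pairs.

```r
library(petdecon)

scenario <- default_scenario()
sim <- simulate_chia_pet(scenario, seed = 7)
sim$pairs
#> <chia_pairs> 36000 read pairs (N++=1508, N+-=1634, N-+=31393, N--=1465)
#> # A tibble: 36,000 × 8
#>    chrom1    pos1 strand1 chrom2    pos2 strand2 label orientation
#>  * <chr>    <dbl> <chr>   <chr>    <dbl> <chr>   <chr> <chr>
#>  1 chr1     99802 -       chr1    100123 +       self  -+
#>  2 chr2    966457 -       chr2    966775 +       self  -+
#>  3 chr1    821999 -       chr1    822324 +       self  -+
#> # ℹ 35,997 more rows
```

Estimate marginal occupancy (a 100 kb training window keeps the example
fast; the default is 5 Mb):

```r
fit <- estimate_occupancy(sim$pairs, window_size = 1e5)
#> Warning message:
#> blind deconvolution did not reach tolerance after 5 rounds (last L1 change 0.366)
fit
#> <occupancy_fit> lambda = 150 bp; h_self = 14.38 bp
glance(fit)
#> # A tibble: 1 × 12
#>   n_pairs n_minus_plus inter_fraction n_self n_inter h_minus_plus h_other lambda
#>     <int>        <int>          <dbl>  <dbl>   <dbl>        <dbl>   <dbl>  <dbl>
#> 1   36000        31393         0.0489 30087.   5913.           10    29.8    150
#> # ℹ 4 more variables: h_self <dbl>, window_chrom <chr>, window_start <dbl>,
#> #   window_end <dbl>
```

The simulator fragments around a modal length of 300 bp, so the true λ
is 150 bp — recovered exactly here. (The convergence warning is
informational: the RSF ridge keeps reshaping slowly after the occupancy
has stabilized; `rounds` can be raised when the last L1 change matters.)

Call interactions at the anchor sites:

```r
res <- detect_interactions(sim$pairs, scenario_anchors(scenario),
                           occupancy_fit = fit)
res$calls
#> <interaction_calls> 20 calls (c = 1.01, single-pair fraction 0)
#> # A tibble: 20 × 15
#>    anchor_id anchor_name anchor_chrom anchor_pos chrom   start     end width
#>  *     <int> <chr>       <chr>             <dbl> <chr>   <dbl>   <dbl> <dbl>
#>  1         1 anchor_1    chr1             100000 chr1   104870  105130   260
#>  2         2 anchor_2    chr1             244440 chr1   304310  304570   260
#>  3         3 anchor_3    chr1             388890 chr1   503760  504020   260
#> # ℹ 17 more rows
#> # ℹ 7 more variables: eloc <dbl>, mass <dbl>, occ_mass <dbl>, support <int>,
#> #   p_value <dbl>, t <dbl>, tau <dbl>
```

All 20 planted loops are recovered: anchor 1 at chr1:100,000 loops to
its planted distal site 5 kb away and the called `eloc` (most likely
jointly occupied location inside the region) lands on it, and so on up
to the 500 kb loop of anchor 10. Diagnostics:

```r
autoplot(fit)                       # occupancy track + RSF heat map
plot_anchor_profile(res$field, 1)   # conditional profile at anchor 1
```

## Command-line interface

`exec/petdecon` wraps the pipeline for shell use:

```sh
petdecon simulate --out data/ --seed 1
petdecon marginal --pairs data/pairs.bedpe --chrom-sizes data/genome.chrom.sizes \
    --out marg/
petdecon calls --pairs data/pairs.bedpe --anchors data/anchors.bed \
    --chrom-sizes data/genome.chrom.sizes --out calls/
petdecon joint --pairs data/pairs.bedpe --chrom-sizes data/genome.chrom.sizes \
    --out joint/ --window-u chr1:95000-115000 --window-v chr1:95000-115000
```

Each run writes a `report.json` with the effective parameters and
headline results; `--config file.yaml` supplies defaults that individual
flags override.

## Tests

```r
# from the source directory
devtools::test()
# or against the installed package
testthat::test_dir("tests/testthat", package = "petdecon",
                   load_package = "installed")
```

The suite covers every module with brute-force oracles (direct-sum KDE
and LSCV, exhaustive binomial enumeration, dense forward convolution)
plus end-to-end acceptance properties: λ recovery across fragment
lengths, mixture-fraction recovery, planted-loop recall and resolution,
the τ fixed-point identity, and type-I control on a noise-only
simulation.

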