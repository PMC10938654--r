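# Formulation registry schema

A registry is a UTF-8 CSV with one row per Kampo extract product:

| column              | type   | meaning                                                 |
|---------------------|--------|---------------------------------------------------------|
| `product_name`      | string | unique product name, matched case-insensitively         |
| `full_daily_dose_g` | number | grams of granule product in one full daily dose (> 0)   |
| *crude columns*     | number | grams of that crude drug per full daily dose (0/empty = absent) |

Any number of crude columns may follow the two fixed columns. The three
columns `scutellariae_radix`, `bupleuri_radix` and `pinelliae_tuber` drive the
exposure-group classification (SR / BR / PT membership); other columns (for
example a lumped `other_crude_g`) are carried but not analyzed.

`kampo_formulary_synthetic.csv` is a SYNTHETIC example registry: product
names are real formulations, but every composition is a placeholder chosen
only to give each product its correct SR/BR/PT membership and plausible
gram amounts. The Shosaikoto row preserves the published BR:PT:SR proportion
of 3.5 : 2.5 : 1.5 (encoded as 7 : 5 : 3 g per full daily dose). Real
manufacturer-specific contents must be supplied by the user for substantive
analyses.
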