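>R2_01
LKKDAWTAEEDDLLVNYINTHGEGNRWSVIAPQLPGRTDNEIKNYINWPSTLK
>R2_02
LKKGAWTAEEDQLLVNYINTHGEGNRWSVIRKQLPGRTDNEIKNYINWNSTLK
>R2_03
LKKGAWTAEEDQLLVMYINTHGEGGRWSVIAKQLPGRTDNEKKNYVNWSSTLK
>R2_04
LKGGAWTAGEDQQLVNYINTHGEGNRWSVIAKQLPGRTDNEIKNYINWNSLLK
>R2_05
LKKGAWTAEEDQLLTHYINSHGEGNRWSVIAKQLPGRTDNEIKNYINWNSTLK
>R2_06
LKKGAWTAEEDQLNVNYINTHGEGNRWSVIADQLPGRTDMEIKNYINWNLTEK
>R2_07
LKKGAWTAEEDQLLVNYITTHGEGNRWSVIAKQLPGRIDNEMKNYVNWNSTLP
>R2_08
LKKGAWTAEEDQLLLNYINTGGEGNRWSVIAKQMPGRTENETKNYINWNSTLK
>R2_09
LKKGAWTAELKQLLVNYIGTHGEGNRWYVIAKPLPGRTDNEIKNYINWNSTGK
>R2_10
NKMGAWTALEDQLLVNYINTHGEENRWSVITGQLPGRTDNEIKNYINWPSTLK
>R2_11
MKKGAWTAEEDRLLVNDINTHGFGNRWSVGAKQLPGRTDNEIKNYINWNSTLK
>R2_12
LKKGAWTAEEDQLLVNYINTHGEGNRWSYIAKQLPGRTDNEIKNPTNWNSTLK
>R3_01
GNVVKFTEEEHRLIAGLQKYGKINWALIARNLPGRTDNAVPNHWNSTLKVKL
>R3_02
GNEVKFTHTEHRLIAGLQKYGKGNWALIARNLPGRTDNAVKNAWNSTLKRKL
>R3_03
GNEVKFTEEEHRLIAGLQKYCKGNWALIARNLPGRTDNAVKNHWNSTLHRKH
>R3_04
KNEVKFTENEHRLIHGLQKYGDGNWALIGFRLPGRTDNAVKNHWNSTVKRKD
>R3_05
GNEVKFTEEEHMLVAALCMYGKGNWHLIRRNLPGRTDNAVIVHWNSTLKRKL
>R3_06
GHEVKFTEAEHDLIKGLQKYGKGNWALVARNLPGRTDNAVNNHWNSTLKRKM
>R3_07
GNEVKFCEEEHRLIAGGFKYGIGQWSLIARSGPGRTDNAGKNHWNSTLKRSQ
>R3_08
GNEVTFTEFDHRLIAGLQKYGKMNWALIARNLPGRTDCAVKNHWNSTLKRKL
>R3_09
GNEVKFTKEEHRLIARLQKYGKDNWAYIARNLPGRTDNAIKNHWNSTLKRKL
>R3_10
GNKVKFTEGEHRLIHGKQKYGKGNWALIARNLPGREDNAVKNHWNSTLHRKL
>R3_11
GNEVKFTEEEHRLIHGLQNYGKGNWALIARVLPGRIVNAVKNHWNSTLGRKL
>R3_12
GNEVMFVESEHRLQAGLQKYGKGNWAMIYRNKHGRTDNAVKNFWNSTLKRYL
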