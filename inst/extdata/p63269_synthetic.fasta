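>P63269-SYNTHETIC GN=Actg2 synthetic scaffold embedding the seven printed Actg2 peptides at their printed coordinates; NOT the real UniProt P63269 sequence
CDQFLDVAKPMYEFPVMQNYCANWAIILELVFPSIVGRPLEEGVMVGMGQKDSYVGESGL
TLLGILTLKYPIEHGNMPYYNWYCESLKAWVKTFTVLQITEGMLVMMDAIMGILIRDCDP
WRRALHCGGLKVMGMTRSPDASYDGHRRFCDISILTYWNDLNRLIKHATEVCVQRTRWLS
AHNHNPQPLPSYVRILTGYSFVTTAEREIVEHALPKMYRGRFWNNQDETFFSCMRPTKFH
PYWCFYTVITIGNERFMSFWQNKQPSFIGMESAGIHETTYAWRKTESWYPMIKWVKVPCI
IGNGQETCVFIMRMQKEITALAPSTMKILQQECGEMAKGHCYQFREQGPGIPCFCKLLRE
KLQECDNGHTIISFRQYMGN
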