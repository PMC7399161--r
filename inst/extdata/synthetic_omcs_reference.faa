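>synthetic_OmcS_reference
KFPEEPEEFCNECHPKDFSMQIAWMRTRRFTWVRAWLLVQGIVQQAYQNMDEQDKVRYMSVDNRLLEPGE
WYFRYKPRYTCAGCHVKVERMVQWGGEISEYVDPRKLLEPSKCTMCHLFILLWQEDWGPMRLGGFWWFLI
TVDYFTSWEAKKQEAPNWPTPQQQRPMQQGFKIMSPAGEWFMFAEFAGGLAYWFILVWSGMVRQLESSKM
TGPNQYQMPTKRLVDTMEFVDGMKTARQPQFAVNISALWWSIGGVRLKEMIRNPTGALKGRSIVDFMFVW
RMIDFKWGLMPSWVIPWYLRQWVWKSKIMVGGSKNQGASAPDPVLEACNDCHASSPFIFKYYSNLMRVNF
NWYLGLKEGCLYCHNYSDFAMMFGCDNCHFPNIMQRMPYWVNFTTGIDMFEVIGERSKDFPMSEGDYSYS
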