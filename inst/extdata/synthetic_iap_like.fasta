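>synthetic_iap_like synthetic IAP-like test protein (not a database record)
MMLLVVMVMMLLLFFVFVAGKSWFQIGCMFWIDKSTVRFVAHAEQSQVFKAHIMQDYADR
TMHMGAGDAKATFEAEFCDSRYTAILVCCDQADRKWILFFWTSALHHCVSLMSETFSCQI
QTCFEDEMTMRQCDWECHAENGTSCWIIIGSAIFIDRAFDGQMGMIEWCEDDHFWCWRAY
YCVWTECQWEIWAYTWGTGLQAWSIIDAWASFHIFKRAEMEDTFACQWIMSFVEASDTGY
RLQKGASFGHMCMTAYWMQMTVAYIYACQQEYYHVKGGEAWKHSALVKYWYQARAMYKKQ
FHQRVLMQQLCWAGWYGTRETAWLGEGFAIVRARSFGEDYCSTVRFMLSAARCGWWAWYV
ERTAQEKMHGAVAKGKIFHIHGQKTAWWKIQGFAWEVVMRGFDQVTCIEQCQHRTVASKC
MTYYRWACMHLVCVFSTAAHLASRTQAMCYCEGEHAFMWIELYFGDWIGTRAERTEWDFA
MIAIVCKFISAWVSTAQMFLTYYSADIIWF
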