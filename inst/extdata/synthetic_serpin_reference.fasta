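>SerpinREF synthetic reference serpin (hinge 345-353, P1 361)
NFSNTSRMWEKRWWRDRLWWWFHGTLSNMFFVKNWERTSYTSKIAESHANSFFPMKYQKTNMWVDEQPNDPIWNHWNAMFYVKKVVNKQAGDSKVLWYYVASDAEAYTQEGRSEGHYREAYPFTLESGSYVIMHPWIDKSILRWANNNWVRLRRNVVYSRVDLRRQSHDYHKINARHEFLIKVIKAMYHAGRRLFRMIVEAEEYMMGFGQDRMAADNINQQKSDDIQIATVKMLTIVVTLTALHRTEMQGRRYFENLIVQKYHQMKMYERFAWSHHMQTKVYPDPHMTQQDDIGKIMGQRQKSFMEFLPIYAHFEMERNHLLKEYAVMQNIQDWHRSYVWMDQWEEGTEAAAAAIPMSIPRSYGNFDGVRMLPAFMQRIA
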