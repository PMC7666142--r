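date,group,min_rate,max_rate,printed_spread,source
June 09,PRK,0.7,1.7,,previous
June 09,EUB,0.7,1.7,,previous
June 09,ROSEO,0.9,2.9,,previous
June 09,SAR11,0.1,1.8,,previous
June 09,GAMMA,1.0,3.6,,previous
June 09,ALT,2.3,5.4,,previous
June 09,NOR5,1.7,2.8,,previous
June 09,CFB,0.7,1.5,,previous
June 09,AAP,1.6,3.7,,previous
July 09,PRK,0.2,1.3,,previous
July 09,EUB,0.2,1.3,,previous
July 09,ROSEO,0.3,1.9,,previous
July 09,SAR11,0.1,1.5,,previous
July 09,GAMMA,1.0,3.4,,previous
July 09,ALT,1.4,5.8,,previous
July 09,NOR5,1.3,2.9,,previous
July 09,CFB,0.5,1.6,,previous
July 09,AAP,0.3,2.4,,previous
May 10,PRK,0.3,1.7,,previous
May 10,EUB,0.2,1.5,,previous
May 10,ROSEO,0.5,3.7,,previous
May 10,SAR11,0.5,1.5,,previous
May 10,GAMMA,1.0,2.7,,previous
May 10,ALT,1.0,4.7,,previous
May 10,NOR5,0.6,2.3,,previous
May 10,CFB,0.2,2.2,,previous
May 10,AAP,1.2,5.9,,previous
July 11,PRK,0.2,0.6,,previous
July 11,EUB,0.2,0.7,,previous
July 11,ROSEO,0.4,1.8,,previous
July 11,SAR11,0.1,0.5,,previous
July 11,GAMMA,0.5,1.5,,previous
July 11,ALT,0.4,3.4,,previous
July 11,NOR5,0.2,1.3,,previous
July 11,CFB,0.2,0.6,,previous
July 11,AAP,0.5,2.2,,previous
February 17,PRK,0.1,0.8,,this_study
February 17,EUB,0.0,0.8,,this_study
February 17,ROSEO,0.5,1.0,,this_study
February 17,SAR11,0.0,0.9,,this_study
February 17,GAMMA,0.2,4.5,,this_study
February 17,ALT,0.1,4.9,,this_study
February 17,NOR5,0.2,0.6,,this_study
February 17,CFB,0.1,1.6,,this_study
February 17,AAP,0.8,1.4,,this_study
April 17,PRK,0.1,0.3,,this_study
April 17,EUB,0.1,0.3,,this_study
April 17,ROSEO,0.1,0.6,,this_study
April 17,SAR11,0.2,0.6,,this_study
April 17,GAMMA,0.3,1.2,,this_study
April 17,ALT,0.5,3.0,,this_study
April 17,NOR5,0.3,1.3,,this_study
April 17,CFB,0.2,1.0,,this_study
April 17,AAP,0.2,0.6,,this_study
July 17,PRK,0.4,0.8,,this_study
July 17,EUB,0.6,0.9,,this_study
July 17,ROSEO,0.4,0.8,,this_study
July 17,SAR11,0.2,0.4,,this_study
July 17,GAMMA,1.0,2.4,,this_study
July 17,ALT,0.4,1.9,,this_study
July 17,NOR5,0.7,1.1,,this_study
July 17,CFB,0.4,0.7,,this_study
July 17,AAP,0.4,0.5,,this_study
November 17,PRK,0.1,0.4,,this_study
November 17,EUB,0.1,0.4,,this_study
November 17,ROSEO,0.2,0.6,,this_study
November 17,SAR11,0.0,0.5,,this_study
November 17,GAMMA,0.1,1.3,,this_study
November 17,ALT,0.0,1.8,,this_study
November 17,NOR5,0.3,0.7,,this_study
November 17,CFB,0.1,0.5,,this_study
November 17,AAP,0.5,1.2,,this_study
Range,PRK,0.1,1.7,1.6,overall
Range,EUB,0.02,1.7,1.7,overall
Range,ROSEO,0.1,2.9,2.8,overall
Range,SAR11,0.03,1.8,1.8,overall
Range,GAMMA,0.2,4.5,4.3,overall
Range,ALT,0.1,5.8,5.7,overall
Range,NOR5,0.2,2.9,2.7,overall
Range,CFB,0.1,2.2,2.1,overall
Range,AAP,0.2,5.9,5.7,overall
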