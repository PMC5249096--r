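<?xml version="1.0" encoding="UTF-8"?>
<Tracks nTracks="1" frameInterval="0.03333333333" spaceUnits="micron" timeUnits="sec">
  <particle nSpots="41">
    <detection t="0" x="0" y="0" z="0"/>
    <detection t="1" x="-1.463873258" y="0.1057391421" z="0"/>
    <detection t="2" x="-1.884914791" y="-0.3572297279" z="0"/>
    <detection t="3" x="-2.584263042" y="0.4340800909" z="0"/>
    <detection t="4" x="-2.946007597" y="0.8036455304" z="0"/>
    <detection t="5" x="-2.988187715" y="0.5775994949" z="0"/>
    <detection t="6" x="-3.615497275" y="0.2843629547" z="0"/>
    <detection t="7" x="-5.107511466" y="-0.5451133738" z="0"/>
    <detection t="8" x="-4.929448336" y="-0.6723392945" z="0"/>
    <detection t="9" x="-4.41180419" y="-0.1098609099" z="0"/>
    <detection t="10" x="-3.262768115" y="-0.4473206318" z="0"/>
    <detection t="11" x="-3.05137229" y="-0.4470694058" z="0"/>
    <detection t="12" x="-4.723771125" y="0.03103377161" z="0"/>
    <detection t="13" x="-5.899666408" y="-0.7422815494" z="0"/>
    <detection t="14" x="-5.210107599" y="-0.6861337491" z="0"/>
    <detection t="15" x="-5.004264611" y="-1.495435854" z="0"/>
    <detection t="16" x="-7.147027918" y="-2.017620882" z="0"/>
    <detection t="17" x="-7.992946985" y="-2.293110778" z="0"/>
    <detection t="18" x="-9.075213916" y="-1.846700015" z="0"/>
    <detection t="19" x="-9.3051731" y="-1.854038477" z="0"/>
    <detection t="20" x="-9.726664148" y="-3.459504623" z="0"/>
    <detection t="21" x="-10.05001122" y="-3.780379547" z="0"/>
    <detection t="22" x="-10.64340649" y="-3.598410462" z="0"/>
    <detection t="23" x="-11.15226021" y="-3.847545036" z="0"/>
    <detection t="24" x="-11.86422424" y="-4.052795981" z="0"/>
    <detection t="25" x="-11.69807354" y="-5.099184342" z="0"/>
    <detection t="26" x="-11.33843136" y="-5.00574526" z="0"/>
    <detection t="27" x="-10.75068988" y="-3.858122837" z="0"/>
    <detection t="28" x="-10.83432184" y="-3.477652127" z="0"/>
    <detection t="29" x="-9.993198304" y="-3.622998263" z="0"/>
    <detection t="30" x="-11.54478708" y="-3.188083913" z="0"/>
    <detection t="31" x="-11.959695" y="-2.234761019" z="0"/>
    <detection t="32" x="-12.11950529" y="-2.037873739" z="0"/>
    <detection t="33" x="-12.70176475" y="-2.073210428" z="0"/>
    <detection t="34" x="-11.39156302" y="-1.374234978" z="0"/>
    <detection t="35" x="-11.33368508" y="-1.940461958" z="0"/>
    <detection t="36" x="-11.78032664" y="-1.565800002" z="0"/>
    <detection t="37" x="-11.75961495" y="-2.602757942" z="0"/>
    <detection t="38" x="-12.13682799" y="-2.673145473" z="0"/>
    <detection t="39" x="-11.94145624" y="-3.248786398" z="0"/>
    <detection t="40" x="-10.58146456" y="-3.698328553" z="0"/>
  </particle>
</Tracks>
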